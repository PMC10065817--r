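# Shared fixtures and independent oracles, all built in code.

toy_panel <- function(n_endo = 3L, n_hk = 2L,
                      concs = c(128, 32, 8, 2, 0.5, 0.125),
                      n_neg = 4L, name = "TOY") {
  probes <- data.frame(
    probe_id = c(sprintf("E%02d", seq_len(n_endo)),
                 sprintf("H%02d", seq_len(n_hk)),
                 sprintf("P%02d", seq_along(concs)),
                 sprintf("N%02d", seq_len(n_neg))),
    gene_symbol = c(sprintf("GENE%02d", seq_len(n_endo)),
                    sprintf("HK%02d", seq_len(n_hk)),
                    sprintf("POS%02d", seq_along(concs)),
                    sprintf("NEG%02d", seq_len(n_neg))),
    code_class = rep(c("Endogenous", "Housekeeping", "Positive",
                       "Negative"),
                     c(n_endo, n_hk, length(concs), n_neg)),
    concentration_fM = c(rep(NA, n_endo + n_hk), concs, rep(NA, n_neg)),
    stringsAsFactors = FALSE
  )
  panel_definition(name, probes)
}

# One lane with controllable blocks; defaults are fully in-window:
# positives are exact powers of two (R^2 = 1), negatives constant 1.
toy_lane <- function(panel, id, endo = 500, hk = 512,
                     pos = c(1024, 256, 64, 16, 4, 1), neg = 1,
                     fov = c(490L, 490L), bd = 1.0) {
  ids <- panel$probes$probe_id
  cls <- panel$probes$code_class
  counts <- integer(length(ids))
  counts[cls == "Endogenous"] <- endo
  counts[cls == "Housekeeping"] <- hk
  counts[cls == "Positive"] <- pos
  counts[cls == "Negative"] <- neg
  names(counts) <- ids
  lane_record(id, fov[1], fov[2], bd, counts)
}

# The 12-lane QC fixture with a hand-derived exclusion set (see
# test-qc.R / test-acceptance.R for the per-lane reasoning).
qc_fixture <- function() {
  panel <- toy_panel()
  lanes <- list(
    toy_lane(panel, "L01"),
    toy_lane(panel, "L02", fov = c(490L, 300L)),              # imaging
    toy_lane(panel, "L03", bd = 2.5),                         # bd, excepted
    toy_lane(panel, "L04", bd = 2.5, pos = rep(32, 6)),       # bd + flat pos
    toy_lane(panel, "L05", bd = 0.05),                        # bd, excepted
    toy_lane(panel, "L06", pos = rep(32, 6)),                 # flat pos only
    toy_lane(panel, "L07", neg = 10),                         # LOD fail
    toy_lane(panel, "L08", hk = 25),                          # ref geomean
    toy_lane(panel, "L09", pos = c(64, 16, 4, 2, 1, 1)),      # pos factor
    toy_lane(panel, "L10", hk = 40),                          # content factor
    toy_lane(panel, "L11"),
    toy_lane(panel, "L12")
  )
  meta <- data.frame(
    sample_id = sprintf("L%02d", 1:12),
    diagnosis = rep(c("NoRejection", "BLorTCMR", "AMR"), 4),
    center = "CenterA", stringsAsFactors = FALSE
  )
  assemble_matrix(lanes, panel, meta)
}

qc_fixture_expected_excluded <-
  c("L02", "L04", "L07", "L08", "L09", "L10")

# The printed-in-repo background toy (6 endogenous probes x 4 samples,
# threshold exactly 30); hand enumeration excludes BGP2, BGP4, BGP6.
background_toy_matrix <- function() {
  path <- system.file("extdata", "background_toy_counts.csv",
                      package = "nanoreject")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  concs <- c(128, 32, 8, 2, 0.5, 0.125)
  probes <- data.frame(
    probe_id = raw$probe_id, gene_symbol = raw$probe_id,
    code_class = raw$code_class,
    concentration_fM = ifelse(raw$code_class == "Positive",
                              concs[cumsum(raw$code_class == "Positive")],
                              NA),
    stringsAsFactors = FALSE
  )
  panel <- panel_definition("BGTOY", probes)
  values <- as.matrix(raw[, c("S1", "S2", "S3", "S4")])
  rownames(values) <- raw$probe_id
  samples <- data.frame(sample_id = colnames(values),
                        diagnosis = c("AMR", "AMR", "NoRejection",
                                      "NoRejection"),
                        center = "CenterA", stringsAsFactors = FALSE)
  count_matrix(panel, samples, values, stage = "raw")
}

# Independent brute-force geNorm oracle: recomputes M from its
# definition (mean over partners of the SD of the pairwise log2 ratio)
# at every elimination step, with the same lexicographic tie-break.
genorm_oracle <- function(values, pseudocount = 0.5) {
  if (any(values == 0)) values <- values + pseudocount
  M_of <- function(genes) {
    sapply(genes, function(j) {
      others <- setdiff(genes, j)
      mean(sapply(others, function(l)
        sd(log2(values[j, ] / values[l, ]))))
    })
  }
  remaining <- rownames(values)
  order_out <- character(0)
  m_out <- setNames(numeric(0), character(0))
  while (length(remaining) > 2L) {
    M <- M_of(remaining)
    worst <- sort(names(M)[M == max(M)])[1]
    m_out[worst] <- M[[worst]]
    order_out <- c(order_out, worst)
    remaining <- setdiff(remaining, worst)
  }
  final <- sd(log2(values[remaining[1], ] / values[remaining[2], ]))
  m_out[remaining] <- final
  list(stability_M = m_out[rownames(values)],
       elimination_order = c(order_out, sort(remaining)))
}

# Independent cophenetic oracle: walk the merge list, assigning each
# newly joined pair of leaf sets the merge height.
cophenetic_oracle <- function(tree) {
  n <- length(tree$order)
  members <- vector("list", nrow(tree$merge))
  D <- matrix(0, n, n)
  for (i in seq_len(nrow(tree$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    left <- get(tree$merge[i, 1]); right <- get(tree$merge[i, 2])
    for (a in left) for (b in right)
      D[a, b] <- D[b, a] <- tree$height[i]
    members[[i]] <- c(left, right)
  }
  stats::as.dist(D)
}

# Minimal RCC text fixture: 13 Code_Summary rows (6 pos, 4 neg, 3 endo).
rcc_fixture_lines <- function() {
  c("<Header>", "FileVersion,3.0", "SoftwareVersion,4.0.0.3",
    "</Header>",
    "<Sample_Attributes>", "ID,FIX1", "GeneRLF,FIXPANEL",
    "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", "FovCount,490", "FovCounted,480",
    "BindingDensity,1.25", "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    paste("Positive", sprintf("POS_%s(%g)", LETTERS[1:6],
                              c(128, 32, 8, 2, 0.5, 0.125)),
          sprintf("P%02d", 1:6),
          c(19200, 4800, 1200, 300, 75, 19), sep = ","),
    paste("Negative", sprintf("NEG_%s", LETTERS[1:4]),
          sprintf("N%02d", 1:4), c(4, 6, 2, 5), sep = ","),
    paste("Endogenous", sprintf("GENE%02d", 1:3),
          sprintf("E%02d", 1:3), c(812, 40, 3), sep = ","),
    "</Code_Summary>")
}
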