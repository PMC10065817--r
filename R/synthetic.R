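#' Specify a synthetic nCounter cohort
#'
#' Describes a three-group biopsy cohort (NoRejection / BLorTCMR / AMR)
#' assayed on one synthetic panel, with known ground truth for every
#' quantity the pipeline estimates. Endogenous counts are negative
#' binomial around `size_factor x 2^(baseline + group effect)`;
#' housekeeping genes carry tiered lognormal coefficients of variation and
#' no group effect; positive controls are linear in their spike-in
#' concentration with small lognormal noise; negative controls are Poisson
#' background. The defaults emulate a 32/32/32 cohort on a large
#' (758 endogenous + 12 reference gene) panel with a six-point positive
#' titration containing the 0.5 fM probe used for the limit-of-detection
#' rule.
#'
#' @param n_per_group Named vector of samples per diagnosis group.
#' @param n_endogenous,n_housekeeping,n_positive,n_negative Panel
#'   composition.
#' @param positive_concentrations_fM Descending spike-in series; must
#'   include 0.5 fM.
#' @param pos_counts_per_fM Expected counts per fM for positive probes.
#' @param size_factor_log2_sd SD of per-sample log2 size factors (RNA
#'   input variation).
#' @param dispersion Negative-binomial dispersion of endogenous counts
#'   (variance `mu + dispersion * mu^2`).
#' @param baseline_log2_mean_range Range of endogenous baseline log2 means.
#' @param de_genes Named list: diagnosis group -> named numeric vector of
#'   log2 effects relative to the NoRejection baseline (gene symbol ->
#'   effect). Defaults plant 20 AMR-specific genes at +1.5 log2 and 15
#'   genes shared by both rejection phenotypes at +1.0 log2.
#' @param housekeeping_cv_tiers Coefficients of variation assigned to the
#'   housekeeping genes in order (recycled if short).
#' @param background_mean Poisson mean of negative-control counts.
#' @param panel_name Panel name, also the probe-ID prefix.
#' @param qc_failures Named list sample_id -> failure mode, applied through
#'   [inject_qc_failure()] after generation.
#' @param seed Integer seed; the seed fully determines the dataset.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_group = c(NoRejection = 32, BLorTCMR = 32,
                                           AMR = 32),
                           n_endogenous = 758,
                           n_housekeeping = 12,
                           n_positive = 6,
                           n_negative = 8,
                           positive_concentrations_fM =
                             c(128, 32, 8, 2, 0.5, 0.125),
                           pos_counts_per_fM = 150,
                           size_factor_log2_sd = 0.25,
                           dispersion = 0.05,
                           baseline_log2_mean_range = c(4, 10),
                           de_genes = NULL,
                           housekeeping_cv_tiers =
                             c(0.05, 0.05, 0.05, 0.2, 0.25, 0.3, 0.35,
                               0.4, 0.45, 0.5, 0.55, 0.6),
                           background_mean = 5,
                           panel_name = "SYNPANEL",
                           qc_failures = list(),
                           seed = 1L) {
  n_per_group <- unlist(n_per_group)  # tolerate YAML-style lists
  if (!is.null(de_genes)) de_genes <- lapply(de_genes, unlist)
  stopifnot(all(names(n_per_group) %in% diagnosis_levels()),
            n_endogenous >= 1L, n_housekeeping >= 2L,
            n_positive >= 2L, n_negative >= 2L,
            length(positive_concentrations_fM) == n_positive,
            !is.unsorted(rev(positive_concentrations_fM), strictly = TRUE),
            dispersion >= 0, background_mean >= 0)
  if (!any(positive_concentrations_fM == 0.5))
    stop("positive titration must include the 0.5 fM probe")
  if (is.null(de_genes)) {
    # graded effect sizes, as in real panels where fold changes span a
    # range rather than sitting at one value
    amr <- sprintf("GENE%04d", seq_len(min(20L, n_endogenous)))
    both <- sprintf("GENE%04d", seq.int(21L, length.out =
                      max(0L, min(15L, n_endogenous - 20L))))
    de_genes <- list(
      AMR = c(stats::setNames(seq(0.8, 2.5, length.out = length(amr)),
                              amr),
              stats::setNames(seq(0.6, 1.6, length.out = length(both)),
                              both)),
      BLorTCMR = stats::setNames(seq(0.6, 1.6,
                                     length.out = length(both)), both)
    )
  }
  all_genes <- sprintf("GENE%04d", seq_len(n_endogenous))
  for (grp in names(de_genes)) {
    if (!all(names(de_genes[[grp]]) %in% all_genes))
      stop("de_genes for ", grp, " reference genes outside the panel")
  }
  structure(list(
    n_per_group = n_per_group, n_endogenous = as.integer(n_endogenous),
    n_housekeeping = as.integer(n_housekeeping),
    n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative),
    positive_concentrations_fM = positive_concentrations_fM,
    pos_counts_per_fM = pos_counts_per_fM,
    size_factor_log2_sd = size_factor_log2_sd, dispersion = dispersion,
    baseline_log2_mean_range = baseline_log2_mean_range,
    de_genes = de_genes,
    housekeeping_cv_tiers = housekeeping_cv_tiers,
    background_mean = background_mean, panel_name = panel_name,
    qc_failures = qc_failures, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' A small fast preset of the synthetic cohort
#'
#' 10 samples per group and 60 endogenous genes; used throughout the test
#' suite where full cohort scale is unnecessary.
#'
#' @param ... Overrides passed to [synthetic_spec()].
#' @export
synthetic_spec_fast <- function(...) {
  defaults <- list(
    n_per_group = c(NoRejection = 10, BLorTCMR = 10, AMR = 10),
    n_endogenous = 60L, n_housekeeping = 6L,
    housekeeping_cv_tiers = c(0.05, 0.05, 0.05, 0.3, 0.45, 0.6),
    de_genes = list(
      AMR = stats::setNames(rep(1.5, 8), sprintf("GENE%04d", 1:8)),
      BLorTCMR = stats::setNames(rep(1.0, 5), sprintf("GENE%04d", 9:13))
    )
  )
  args <- defaults
  dots <- list(...)
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]  # replace wholesale
  do.call(synthetic_spec, args)
}

# Canonical housekeeping symbols, enough for any plausible panel size.
hk_symbols <- function(n) {
  base <- c("POLR2A", "GUSB", "SDHA", "HPRT1", "TBP", "PGK1", "RPLP0",
            "ACTB", "B2M", "GAPDH", "HMBS", "UBC")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("REF%02d", seq_len(n - length(base))))
}

synthetic_panel <- function(spec) {
  endo <- sprintf("GENE%04d", seq_len(spec$n_endogenous))
  hk <- hk_symbols(spec$n_housekeeping)
  pos <- sprintf("POS_%s", LETTERS[seq_len(spec$n_positive)])
  neg <- sprintf("NEG_%s", LETTERS[seq_len(spec$n_negative)])
  probes <- data.frame(
    probe_id = paste0(spec$panel_name, ".",
                      c(endo, hk, pos, neg)),
    gene_symbol = c(endo, hk, pos, neg),
    code_class = rep(c("Endogenous", "Housekeeping", "Positive",
                       "Negative"),
                     c(length(endo), length(hk), length(pos),
                       length(neg))),
    concentration_fM = c(rep(NA_real_, length(endo) + length(hk)),
                         spec$positive_concentrations_fM,
                         rep(NA_real_, length(neg))),
    stringsAsFactors = FALSE
  )
  panel_definition(spec$panel_name, probes)
}

# Latent per-gene baselines and per-group effects shared by paired panels.
synthetic_truth_params <- function(spec) {
  endo <- sprintf("GENE%04d", seq_len(spec$n_endogenous))
  baseline <- stats::runif(spec$n_endogenous,
                           spec$baseline_log2_mean_range[1],
                           spec$baseline_log2_mean_range[2])
  names(baseline) <- endo
  # planted effect genes emulate curated panel content: genes picked for
  # a disease panel are reliably detectable, so their baselines are kept
  # above the background regime
  eff_genes <- unique(unlist(lapply(spec$de_genes, names)))
  baseline[eff_genes] <- pmax(baseline[eff_genes], 6)
  effects <- matrix(0, nrow = spec$n_endogenous, ncol = 3,
                    dimnames = list(endo, diagnosis_levels()))
  for (grp in names(spec$de_genes)) {
    eff <- spec$de_genes[[grp]]
    effects[names(eff), grp] <- eff
  }
  hk <- hk_symbols(spec$n_housekeeping)
  hk_baseline <- stats::setNames(
    stats::runif(spec$n_housekeeping, 8, 11), hk)
  hk_cv <- stats::setNames(
    rep_len(spec$housekeeping_cv_tiers, spec$n_housekeeping), hk)
  list(baseline = baseline, effects = effects,
       hk_baseline = hk_baseline, hk_cv = hk_cv)
}

synthetic_samples <- function(spec) {
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    diagnosis = groups,
    center = rep_len(c("CenterA", "CenterB"), n),
    stringsAsFactors = FALSE
  )
}

# Draw one panel's lanes given latent truth; called under an active RNG
# stream so paired panels get independent technical noise.
realize_lanes <- function(spec, panel, samples, params) {
  n <- nrow(samples)
  endo_sym <- names(params$baseline)
  hk_sym <- names(params$hk_baseline)
  sf <- 2^stats::rnorm(n, 0, spec$size_factor_log2_sd)
  size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
  lanes <- vector("list", n)
  probes <- panel$probes
  for (i in seq_len(n)) {
    grp <- samples$diagnosis[i]
    mu_endo <- sf[i] * 2^(params$baseline + params$effects[, grp])
    endo_counts <- if (is.finite(size)) {
      stats::rnbinom(length(mu_endo), mu = mu_endo, size = size)
    } else {
      stats::rpois(length(mu_endo), lambda = mu_endo)
    }
    sdlog <- sqrt(log(1 + params$hk_cv^2))
    hk_counts <- round(sf[i] * 2^params$hk_baseline *
                         exp(stats::rnorm(length(hk_sym), 0, sdlog) -
                               sdlog^2 / 2))
    pos_counts <- round(spec$positive_concentrations_fM *
                          spec$pos_counts_per_fM *
                          exp(stats::rnorm(spec$n_positive, 0, 0.05)))
    neg_counts <- stats::rpois(spec$n_negative, spec$background_mean)
    counts <- c(endo_counts, pmax(hk_counts, 1L), pmax(pos_counts, 1L),
                neg_counts)
    names(counts) <- probes$probe_id
    fov_att <- 490L
    fov_cnt <- fov_att - stats::rbinom(1L, 20L, 0.1)
    bd <- stats::runif(1L, 0.6, 1.9)
    lanes[[i]] <- lane_record(samples$sample_id[i], fov_att, fov_cnt, bd,
                              counts)
  }
  lanes
}

# Signed per-comparison truth derived from the group-effect matrix.
truth_de_table <- function(params) {
  cmp <- list(c("AMR", "NoRejection"), c("AMR", "BLorTCMR"),
              c("BLorTCMR", "NoRejection"))
  out <- list()
  for (pair in cmp) {
    delta <- params$effects[, pair[1]] - params$effects[, pair[2]]
    out[[paste(pair, collapse = "_vs_")]] <- delta[delta != 0]
  }
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `lanes` (list of [lane_record()]), `panel`,
#'   `samples` (sample sheet), and `truth` (true differentially expressed
#'   genes per comparison with signed log2 effects, the housekeeping
#'   stability tiers as true coefficients of variation, and any injected
#'   QC failures).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  panel <- synthetic_panel(spec)
  samples <- synthetic_samples(spec)
  params <- synthetic_truth_params(spec)
  lanes <- realize_lanes(spec, panel, samples, params)
  names(lanes) <- samples$sample_id
  for (sid in names(spec$qc_failures)) {
    if (!sid %in% names(lanes))
      stop("qc_failures names unknown sample '", sid, "'")
    lanes[[sid]] <- inject_qc_failure(lanes[[sid]], panel,
                                      spec$qc_failures[[sid]])
  }
  truth <- list(de_genes = truth_de_table(params),
                reference_cv = params$hk_cv,
                baseline_log2 = params$baseline,
                qc_failures = spec$qc_failures)
  list(lanes = unname(lanes), panel = panel, samples = samples,
       truth = truth)
}

#' Generate two panels of the same cohort from one ground truth
#'
#' Emulates assaying the same biopsies with a large panel and a small
#' AMR-focused subpanel (as with the B-HOT and Elements panels): the two
#' panels share the latent per-sample expression truth and gene symbols
#' but have panel-specific probe IDs, independent technical noise and
#' independent size factors, and the subpanel carries only a subset of
#' endogenous genes (always including every planted effect gene) and a
#' subset of the housekeeping candidates.
#'
#' @param spec A [synthetic_spec()] describing the large panel.
#' @param n_sub_endogenous Endogenous genes on the subpanel.
#' @param n_sub_housekeeping Housekeeping genes on the subpanel.
#' @param sub_name Subpanel name / probe-ID prefix.
#' @return A list with `large` and `small` datasets (each shaped like
#'   [generate_dataset()] output) sharing one `truth`.
#' @export
generate_paired_dataset <- function(spec, n_sub_endogenous = 90L,
                                    n_sub_housekeeping = 6L,
                                    sub_name = "SYNSUB") {
  stopifnot(inherits(spec, "synthetic_spec"),
            n_sub_endogenous <= spec$n_endogenous,
            n_sub_housekeeping <= spec$n_housekeeping)
  set.seed(spec$seed)
  panel <- synthetic_panel(spec)
  samples <- synthetic_samples(spec)
  params <- synthetic_truth_params(spec)
  lanes_large <- realize_lanes(spec, panel, samples, params)

  effect_genes <- unique(unlist(lapply(spec$de_genes, names)))
  others <- setdiff(names(params$baseline), effect_genes)
  extra <- sample(others, max(0L, n_sub_endogenous - length(effect_genes)))
  sub_genes <- sort(c(effect_genes, extra))[seq_len(
    min(n_sub_endogenous, length(effect_genes) + length(extra)))]
  sub_hk <- hk_symbols(spec$n_housekeeping)[seq_len(n_sub_housekeeping)]

  sub_spec <- spec
  sub_spec$panel_name <- sub_name
  sub_spec$n_endogenous <- length(sub_genes)
  sub_spec$n_housekeeping <- length(sub_hk)
  sub_panel <- synthetic_panel(sub_spec)
  # keep the large panel's symbols on the subpanel probes
  keep <- sub_panel$probes$code_class %in% c("Positive", "Negative")
  sub_panel$probes$gene_symbol[!keep] <- c(sub_genes, sub_hk)
  sub_panel$probes$probe_id[!keep] <-
    paste0(sub_name, ".", c(sub_genes, sub_hk))

  names(lanes_large) <- samples$sample_id
  for (sid in names(spec$qc_failures)) {
    if (!sid %in% names(lanes_large))
      stop("qc_failures names unknown sample '", sid, "'")
    lanes_large[[sid]] <- inject_qc_failure(lanes_large[[sid]], panel,
                                            spec$qc_failures[[sid]])
  }
  lanes_large <- unname(lanes_large)

  sub_params <- list(
    baseline = params$baseline[sub_genes],
    effects = params$effects[sub_genes, , drop = FALSE],
    hk_baseline = params$hk_baseline[sub_hk],
    hk_cv = params$hk_cv[sub_hk]
  )
  lanes_small <- realize_lanes(sub_spec, sub_panel, samples, sub_params)

  truth <- list(de_genes = truth_de_table(params),
                reference_cv = params$hk_cv,
                subpanel_genes = sub_genes,
                qc_failures = spec$qc_failures)
  list(
    large = list(lanes = lanes_large, panel = panel, samples = samples,
                 truth = truth),
    small = list(lanes = lanes_small, panel = sub_panel,
                 samples = samples, truth = truth),
    truth = truth
  )
}

#' Deterministically corrupt one lane so a named QC criterion fails
#'
#' @param lane A [lane_record()].
#' @param panel The panel the lane belongs to.
#' @param mode One of `low_fov` (imaging ratio below threshold),
#'   `high_binding_density` / `low_binding_density` (outside the 0.1-2.25
#'   spots/um^2 window), `flat_positives` (all positive probes set to one
#'   value so the titration has no slope), `low_refs` (housekeeping
#'   geometric mean forced under 30 counts).
#' @return The mutated [lane_record()].
#' @export
inject_qc_failure <- function(lane, panel,
                              mode = c("low_fov", "high_binding_density",
                                       "low_binding_density",
                                       "flat_positives", "low_refs")) {
  mode <- match.arg(mode)
  counts <- lane$counts
  fov_counted <- lane$fov_counted
  bd <- lane$binding_density
  pos_ids <- panel_probe_ids(panel, "Positive")
  hk_ids <- panel_probe_ids(panel, "Housekeeping")
  switch(mode,
    low_fov = { fov_counted <- as.integer(floor(0.5 * lane$fov_attempted)) },
    high_binding_density = { bd <- 2.5 },
    low_binding_density = { bd <- 0.05 },
    flat_positives = { counts[pos_ids] <- 500L },
    low_refs = { counts[hk_ids] <- 10L }
  )
  lane_record(lane$sample_id, lane$fov_attempted, fov_counted, bd, counts)
}

#' Write a synthetic dataset to disk
#'
#' Emits one RCC file per lane, the panel definition CSV, the sample
#' sheet CSV, and the ground truth as JSON.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lane in dataset$lanes)
    write_rcc(lane, dataset$panel,
              file.path(dir, paste0(lane$sample_id, ".RCC")))
  write_panel(dataset$panel, file.path(dir, "panel.csv"))
  utils::write.csv(dataset$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `*.RCC`, `panel.csv` and `samples.csv`.
#' @return A raw-stage [count_matrix()].
#' @export
read_dataset <- function(dir) {
  panel <- read_panel(file.path(dir, "panel.csv"), name = "panel")
  samples <- read_sample_sheet(file.path(dir, "samples.csv"))
  files <- list.files(dir, pattern = "\\.RCC$", full.names = TRUE)
  lanes <- lapply(files, read_rcc)
  assemble_matrix(lanes, panel, samples)
}
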