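#' geNorm stability ranking of reference-gene candidates
#'
#' For candidate genes j and k, the pairwise variation V_jk is the
#' standard deviation over samples of log2(x_j / x_k); the stability of
#' gene j is M_j, the mean of V_jk over all other candidates k. The least
#' stable gene (highest M) is removed and M recomputed, iterating until
#' two genes remain; those two share the M of the final two-gene stage.
#' Lower M means more stable. The selected references are the `k` genes
#' eliminated last. The pairwise-variation series V(m/m+1) between
#' normalization factors built from the m and m+1 most stable genes is
#' reported for diagnostics but plays no role in selection (the number of
#' references is fixed by `k`).
#'
#' @param values Candidates x samples matrix of strictly positive values
#'   (rows named by gene); if any zero occurs, `pseudocount` is added to
#'   every entry of the candidate rows.
#' @param k Number of references to select (default 3).
#' @param pseudocount Added only when a zero count occurs (default 0.5).
#' @return A `genorm_result`: `stability_M` (per-gene M at elimination
#'   time), `initial_M` (M with all candidates present),
#'   `pairwise_variation` (V_jk matrix), `elimination_order` (first
#'   removed first; the final pair is reported jointly at the end, in
#'   lexicographic order), `selected_references`, and `vk`
#'   (V(m/m+1) series).
#' @export
genorm_rank <- function(values, k = 3L, pseudocount = 0.5) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  genes <- rownames(values)
  if (length(genes) < 3L)
    stop("geNorm needs at least 3 candidate genes")
  if (anyDuplicated(genes)) stop("candidate gene names must be unique")
  if (k > length(genes))
    stop("k cannot exceed the candidate count")
  if (any(values < 0)) stop("counts must be nonnegative")
  if (any(values == 0)) {
    if (is.null(pseudocount))
      stop("zero counts among candidates and no pseudocount configured")
    values <- values + pseudocount
  }
  lv <- log2(values)

  pair_sd <- function(lv) {
    g <- nrow(lv)
    V <- matrix(0, g, g, dimnames = list(rownames(lv), rownames(lv)))
    for (j in seq_len(g - 1L)) {
      for (l in seq.int(j + 1L, g)) {
        V[j, l] <- V[l, j] <- stats::sd(lv[j, ] - lv[l, ])
      }
    }
    V
  }
  m_values <- function(V) rowSums(V) / (nrow(V) - 1L)

  V_full <- pair_sd(lv)
  initial_M <- m_values(V_full)
  stability_M <- stats::setNames(rep(NA_real_, length(genes)), genes)
  elimination <- character(0)
  remaining <- genes
  while (length(remaining) > 2L) {
    M <- m_values(pair_sd(lv[remaining, , drop = FALSE]))
    worst <- names(M)[M == max(M)]
    worst <- sort(worst)[1L]  # deterministic tie-break
    stability_M[worst] <- M[[worst]]
    elimination <- c(elimination, worst)
    remaining <- setdiff(remaining, worst)
  }
  final_M <- stats::sd(lv[remaining[1], ] - lv[remaining[2], ])
  stability_M[remaining] <- final_M
  elimination <- c(elimination, sort(remaining))

  selected <- rev(elimination)[seq_len(k)]
  selected <- selected[order(stability_M[selected],
                             selected)]  # most stable first

  # V(m/m+1): SD over samples of log2 ratio of normalization factors
  # (geometric means of the m vs m+1 most stable genes).
  ranked <- rev(elimination)
  vk <- numeric(0)
  for (m in seq.int(2L, length(genes) - 1L)) {
    nf_m <- colMeans(lv[ranked[seq_len(m)], , drop = FALSE])
    nf_m1 <- colMeans(lv[ranked[seq_len(m + 1L)], , drop = FALSE])
    vk[sprintf("V%d/%d", m, m + 1L)] <- stats::sd(nf_m - nf_m1)
  }

  structure(list(
    stability_M = stability_M, initial_M = initial_M,
    pairwise_variation = V_full,
    elimination_order = elimination,
    selected_references = selected, vk = vk,
    k = as.integer(k)), class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm ranking of", length(x$stability_M), "candidates\n")
  sel <- x$selected_references
  cat("  selected references:",
      paste(sprintf("%s (M=%.3f)", sel, x$stability_M[sel]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Positive-control (technical) normalization
#'
#' Scales each sample by its technical factor (cohort mean of
#' positive-probe geometric means over the sample's own geometric mean).
#'
#' @param mat A raw-stage [count_matrix()].
#' @return The matrix at stage `pos_normalized`, with a `pos_factors`
#'   attribute.
#' @export
pos_normalize <- function(mat) {
  stopifnot(inherits(mat, "count_matrix"), mat$stage == "raw")
  f <- technical_norm_factor(mat)
  out <- count_matrix(mat$panel, mat$samples,
                      sweep(mat$values, 2, f, `*`),
                      stage = "pos_normalized")
  attr(out, "pos_factors") <- f
  out
}

#' Reference-gene (content) normalization
#'
#' Scales each sample by its content factor: the cohort's arithmetic mean
#' of reference-gene geometric means divided by the sample's own
#' reference geometric mean. After normalization the reference geometric
#' mean is identical across samples.
#'
#' @param mat A [count_matrix()] (typically `pos_normalized`).
#' @param references Reference genes: probe IDs or gene symbols.
#' @return The matrix at stage `content_normalized`, with
#'   `content_factors`, `pos_factors` (carried through) and
#'   `references_used` attributes.
#' @export
content_normalize <- function(mat, references) {
  stopifnot(inherits(mat, "count_matrix"))
  probes <- mat$panel$probes
  ref_ids <- ifelse(references %in% probes$probe_id, references,
                    probes$probe_id[match(references,
                                          probes$gene_symbol)])
  if (any(is.na(ref_ids)) || !all(ref_ids %in% rownames(mat$values)))
    stop("reference gene(s) not present in the matrix: ",
         paste(references[is.na(ref_ids) |
                            !(ref_ids %in% rownames(mat$values))],
               collapse = ", "))
  f <- norm_factors(mat$values[ref_ids, , drop = FALSE])
  out <- count_matrix(mat$panel, mat$samples,
                      sweep(mat$values, 2, f, `*`),
                      stage = "content_normalized")
  attr(out, "content_factors") <- f
  attr(out, "pos_factors") <- attr(mat, "pos_factors")
  attr(out, "references_used") <- unname(ref_ids)
  out
}

#' Two-step normalization with geNorm reference selection
#'
#' Applies the positive-control technical factor, ranks the housekeeping
#' candidates with geNorm on the technically normalized counts, selects
#' the `k` most stable references, and applies the content factor
#' computed from them.
#'
#' @param mat A raw-stage [count_matrix()].
#' @param k Number of references (default 3).
#' @param use_positives Apply the positive-control step first (default);
#'   when `FALSE` the content factor is computed on raw counts.
#' @param pseudocount Passed to [genorm_rank()].
#' @return A list: `norm` (the `content_normalized` matrix), `genorm`
#'   (the [genorm_rank()] result, named by gene symbol), `references`
#'   (probe IDs used), `pos_factors`, `content_factors`.
#' @export
normalize_matrix <- function(mat, k = 3L, use_positives = TRUE,
                             pseudocount = 0.5) {
  stopifnot(inherits(mat, "count_matrix"), mat$stage == "raw")
  step1 <- if (use_positives) pos_normalize(mat) else mat
  hk_ids <- matrix_rows(step1, "Housekeeping")
  if (length(hk_ids) < 3L)
    stop("fewer than 3 housekeeping candidates on the panel")
  cand <- step1$values[hk_ids, , drop = FALSE]
  rownames(cand) <- step1$panel$probes$gene_symbol[
    match(hk_ids, step1$panel$probes$probe_id)]
  gn <- genorm_rank(cand, k = k, pseudocount = pseudocount)
  norm <- content_normalize(step1, gn$selected_references)
  list(norm = norm, genorm = gn,
       references = attr(norm, "references_used"),
       pos_factors = attr(step1, "pos_factors"),
       content_factors = attr(norm, "content_factors"))
}
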