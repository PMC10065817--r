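#' Per-sample background level
#'
#' The background of a sample is the mean of its negative-control probes
#' plus two sample standard deviations (the multiplier is configurable).
#'
#' @param negative_counts Negative-control counts of one sample (>= 2).
#' @param sd_multiplier SD multiplier (default 2).
#' @return Nonnegative scalar.
#' @export
sample_background <- function(negative_counts, sd_multiplier = 2) {
  if (length(negative_counts) < 2L)
    stop("background needs at least 2 negative-control probes")
  mean(negative_counts) + sd_multiplier * sample_sd(negative_counts)
}

#' Study-level background threshold and probe filter
#'
#' The study threshold is twice the highest per-sample background.
#' An endogenous probe is excluded when its count falls below the
#' threshold in at least 50% of the samples (inclusive: `>= ceiling(n/2)`
#' samples). Housekeeping probes failing the same rule are flagged but
#' retained, so reference-gene candidacy remains auditable rather than
#' silently altered; control probes are never part of the excluded list.
#'
#' @param mat A QC-passed raw-stage [count_matrix()].
#' @param sd_multiplier SD multiplier of the per-sample background.
#' @return A `background_result` list: `per_sample_background`,
#'   `study_threshold`, `excluded_probes` (endogenous probe IDs),
#'   `flagged_housekeeping`, and `kept_matrix` (survivors plus all
#'   control and housekeeping probes).
#' @export
apply_probe_filter <- function(mat, sd_multiplier = 2) {
  stopifnot(inherits(mat, "count_matrix"))
  neg_ids <- matrix_rows(mat, "Negative")
  backgrounds <- apply(mat$values[neg_ids, , drop = FALSE], 2,
                       sample_background, sd_multiplier = sd_multiplier)
  threshold <- 2 * max(backgrounds)
  n <- ncol(mat$values)
  need <- ceiling(n / 2)
  below <- rowSums(mat$values < threshold)

  endo_ids <- matrix_rows(mat, "Endogenous")
  hk_ids <- matrix_rows(mat, "Housekeeping")
  excluded <- endo_ids[below[endo_ids] >= need]
  flagged_hk <- hk_ids[below[hk_ids] >= need]

  keep <- setdiff(rownames(mat$values), excluded)
  kept <- count_matrix(mat$panel,
                       mat$samples,
                       mat$values[keep, , drop = FALSE],
                       stage = mat$stage)
  structure(list(
    per_sample_background = backgrounds,
    study_threshold = threshold,
    excluded_probes = excluded,
    flagged_housekeeping = flagged_hk,
    kept_matrix = kept), class = "background_result")
}

#' @export
print.background_result <- function(x, ...) {
  cat(sprintf(
    "background threshold %.3f (2 x max per-sample background)\n",
    x$study_threshold))
  cat(sprintf("  %d endogenous probe(s) excluded, %d housekeeping flagged\n",
              length(x$excluded_probes), length(x$flagged_housekeeping)))
  invisible(x)
}
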