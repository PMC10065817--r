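#' Lane-level quality-control thresholds
#'
#' The default flag windows follow the platform's standard settings: an
#' imaging pass when at least 75% of attempted fields of view are counted,
#' binding density inside 0.1-2.25 spots/um^2, positive-control titration
#' linearity R^2 above 0.95, a limit-of-detection rule requiring the 0.5 fM
#' positive probe to sit at least 2 SDs above the negative-control mean, a
#' positive-control (technical) normalization factor inside 0.1-2.0, a
#' reference-gene (content) normalization factor inside 0.1-8.0, and a
#' minimum reference-gene geometric mean of 30 counts.
#'
#' @param fov_pass_ratio Minimum counted/attempted FOV ratio.
#' @param binding_density_window Acceptance window, spots/um^2.
#' @param pos_linearity_min_r2 Minimum titration R^2.
#' @param lod_sd_multiplier SD multiplier in the limit-of-detection rule.
#' @param pos_norm_factor_window Technical correction-factor window.
#' @param content_norm_factor_window Content correction-factor window.
#' @param refgene_geomean_min_counts Minimum housekeeping geometric mean.
#' @param exclude_on_lod Whether a limit-of-detection failure excludes the
#'   sample (default) or only flags it.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(fov_pass_ratio = 0.75,
                          binding_density_window = c(0.1, 2.25),
                          pos_linearity_min_r2 = 0.95,
                          lod_sd_multiplier = 2,
                          pos_norm_factor_window = c(0.1, 2.0),
                          content_norm_factor_window = c(0.1, 8.0),
                          refgene_geomean_min_counts = 30,
                          exclude_on_lod = TRUE) {
  stopifnot(fov_pass_ratio > 0, fov_pass_ratio <= 1,
            diff(binding_density_window) > 0,
            diff(pos_norm_factor_window) > 0,
            diff(content_norm_factor_window) > 0,
            lod_sd_multiplier > 0)
  structure(list(
    fov_pass_ratio = fov_pass_ratio,
    binding_density_window = binding_density_window,
    pos_linearity_min_r2 = pos_linearity_min_r2,
    lod_sd_multiplier = lod_sd_multiplier,
    pos_norm_factor_window = pos_norm_factor_window,
    content_norm_factor_window = content_norm_factor_window,
    refgene_geomean_min_counts = refgene_geomean_min_counts,
    exclude_on_lod = exclude_on_lod), class = "qc_thresholds")
}

#' Positive-control titration linearity
#'
#' R^2 of the least-squares fit of log2(count) on log2(concentration)
#' across the positive probes. A degenerate titration (all counts equal,
#' so the response carries no variance) is reported as R^2 = 0 with a
#' `degenerate` attribute.
#'
#' @param counts Positive-probe counts.
#' @param concentrations_fM Matching spike-in concentrations.
#' @return R^2 in `[0, 1]`.
#' @export
pos_control_linearity <- function(counts, concentrations_fM) {
  stopifnot(length(counts) == length(concentrations_fM),
            length(counts) >= 3L,
            anyDuplicated(concentrations_fM) == 0L)
  y <- log2(pmax(counts, 0.5))
  if (stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  x <- log2(concentrations_fM)
  structure(unname(stats::cor(x, y)^2), degenerate = FALSE)
}

#' Limit-of-detection check
#'
#' Passes when the 0.5 fM positive probe counts at least
#' `lod_sd_multiplier` sample SDs above the mean of the negative controls.
#'
#' @param pos_05_count Count of the 0.5 fM positive probe.
#' @param negative_counts Negative-control counts.
#' @param sd_multiplier SD multiplier (default 2).
#' @return Logical.
#' @export
limit_of_detection <- function(pos_05_count, negative_counts,
                               sd_multiplier = 2) {
  stopifnot(length(negative_counts) >= 2L)
  pos_05_count >= mean(negative_counts) +
    sd_multiplier * sample_sd(negative_counts)
}

#' Per-sample normalization factors against a cohort anchor
#'
#' The factor for sample i is the cohort's arithmetic mean of per-sample
#' geometric means divided by sample i's geometric mean, so that
#' multiplying each sample by its factor equalizes the geometric means at
#' the cohort mean. Used for both the positive-control (technical) factor
#' and the reference-gene (content) factor.
#'
#' @param values Probes x samples matrix restricted to the anchor probes.
#' @return Named per-sample factor vector.
#' @export
norm_factors <- function(values) {
  if (any(values <= 0))
    stop("normalization factors need strictly positive counts")
  g <- apply(values, 2, geomean)
  mean(g) / g
}

#' @rdname norm_factors
#' @param mat A raw-stage [count_matrix()].
#' @export
technical_norm_factor <- function(mat) {
  norm_factors(mat$values[matrix_rows(mat, "Positive"), , drop = FALSE])
}

#' Lane QC report
#'
#' Computes every lane metric and applies the exclusion rules: a sample is
#' excluded when its technical or content normalization factor falls
#' outside its window, its housekeeping geometric mean is under the
#' minimum, the imaging ratio or limit of detection fails, or the binding
#' density is out of window — except that an out-of-window binding density
#' alone is accepted when titration linearity exceeds its minimum and both
#' normalization factors are in-window (the binding-density exception).
#' Metric violations that do not trigger exclusion (titration linearity,
#' an excepted binding density) are still flagged.
#'
#' @param mat A raw-stage [count_matrix()] with lane attributes.
#' @param ref_candidates Probe IDs of the reference-gene candidates
#'   (default: the panel's Housekeeping probes).
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_report` data.frame, one row per sample.
#' @export
lane_qc <- function(mat, ref_candidates = NULL,
                    thresholds = qc_thresholds()) {
  stopifnot(inherits(mat, "count_matrix"), mat$stage == "raw")
  th <- thresholds
  s <- mat$samples
  n <- nrow(s)
  pos_ids <- matrix_rows(mat, "Positive")
  neg_ids <- matrix_rows(mat, "Negative")
  if (is.null(ref_candidates)) ref_candidates <- matrix_rows(mat, "Housekeeping")
  concs <- mat$panel$probes$concentration_fM[
    match(pos_ids, mat$panel$probes$probe_id)]
  id05 <- pos_ids[which(concs == 0.5)]
  if (length(id05) != 1L)
    stop("panel must carry exactly one 0.5 fM positive probe")

  fov_ratio <- s$fov_counted / s$fov_attempted
  binding_density <- s$binding_density
  pos_r2 <- vapply(seq_len(n), function(i)
    as.numeric(pos_control_linearity(mat$values[pos_ids, i], concs)), 1.0)
  lod_pass <- vapply(seq_len(n), function(i)
    limit_of_detection(mat$values[id05, i], mat$values[neg_ids, i],
                       th$lod_sd_multiplier), TRUE)
  pos_factor <- technical_norm_factor(mat)
  # content factor on technically normalized housekeeping counts
  hk_pos_norm <- sweep(mat$values[ref_candidates, , drop = FALSE], 2,
                       pos_factor, `*`)
  content_factor <- norm_factors(hk_pos_norm)
  refgene_geomean <- apply(mat$values[ref_candidates, , drop = FALSE], 2,
                           geomean)

  in_win <- function(x, w) x >= w[1] & x <= w[2]
  f_imaging <- fov_ratio < th$fov_pass_ratio
  f_bd <- !in_win(binding_density, th$binding_density_window)
  f_r2 <- pos_r2 <= th$pos_linearity_min_r2
  f_lod <- !lod_pass
  f_pos <- !in_win(pos_factor, th$pos_norm_factor_window)
  f_content <- !in_win(content_factor, th$content_norm_factor_window)
  f_refgm <- refgene_geomean < th$refgene_geomean_min_counts

  bd_exception_met <- !f_r2 & !f_pos & !f_content
  excluded <- f_imaging | f_pos | f_content | f_refgm |
    (f_bd & !bd_exception_met) | (f_lod & th$exclude_on_lod)

  reason_of <- list(
    imaging = sprintf("FOV ratio %.3f < %.2f", fov_ratio,
                      th$fov_pass_ratio),
    binding_density = sprintf(
      "binding density %.3f outside [%g, %g] and exception not met",
      binding_density, th$binding_density_window[1],
      th$binding_density_window[2]),
    lod = sprintf("0.5 fM positive below negative mean + %g SD",
                  th$lod_sd_multiplier),
    pos_norm_factor = sprintf(
      "positive-control factor %.3f outside [%g, %g]", pos_factor,
      th$pos_norm_factor_window[1], th$pos_norm_factor_window[2]),
    content_norm_factor = sprintf(
      "content factor %.3f outside [%g, %g]", content_factor,
      th$content_norm_factor_window[1], th$content_norm_factor_window[2]),
    refgene_geomean = sprintf("reference geomean %.1f < %g",
                              refgene_geomean,
                              th$refgene_geomean_min_counts)
  )
  flag_mat <- cbind(imaging = f_imaging, binding_density = f_bd,
                    pos_linearity = f_r2, lod = f_lod,
                    pos_norm_factor = f_pos,
                    content_norm_factor = f_content,
                    refgene_geomean = f_refgm)
  excl_mat <- cbind(imaging = f_imaging,
                    binding_density = f_bd & !bd_exception_met,
                    lod = f_lod & th$exclude_on_lod,
                    pos_norm_factor = f_pos,
                    content_norm_factor = f_content,
                    refgene_geomean = f_refgm)
  flags <- apply(flag_mat, 1, function(r)
    paste(colnames(flag_mat)[r], collapse = ";"))
  reasons <- vapply(seq_len(n), function(i) {
    on <- colnames(excl_mat)[excl_mat[i, ]]
    paste(vapply(on, function(k) reason_of[[k]][i], ""), collapse = "; ")
  }, "")

  report <- data.frame(
    sample_id = s$sample_id, fov_ratio = fov_ratio,
    binding_density = binding_density, pos_r2 = pos_r2,
    lod_pass = lod_pass, pos_norm_factor = unname(pos_factor),
    content_norm_factor = unname(content_factor),
    refgene_geomean = unname(refgene_geomean),
    flags = flags, excluded = unname(excluded), reasons = reasons,
    stringsAsFactors = FALSE
  )
  class(report) <- c("qc_report", "data.frame")
  attr(report, "thresholds") <- th
  report
}

#' Drop QC-excluded samples from a matrix
#'
#' @param mat A [count_matrix()].
#' @param report The [lane_qc()] report for the same samples.
#' @return The matrix restricted to surviving samples, order preserved.
#' @export
filter_samples <- function(mat, report) {
  stopifnot(inherits(mat, "count_matrix"))
  if (!setequal(report$sample_id, mat$samples$sample_id))
    stop("QC report does not cover the matrix samples")
  excluded <- report$excluded[match(mat$samples$sample_id,
                                    report$sample_id)]
  if (all(excluded)) stop("all samples excluded by QC: empty cohort")
  subset_samples(mat, !excluded)
}
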