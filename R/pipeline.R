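#' Pipeline configuration
#'
#' Collects every stage's options for an end-to-end run. The input is
#' either a directory of RCC files (plus `panel.csv` and `samples.csv`)
#' or a synthetic-cohort specification. A single global seed
#' deterministically derives per-stage seeds (via [stage_seed()]), so a
#' stage can be rerun in isolation and a full rerun is bit-identical.
#'
#' @param input Either `list(dir = path)` or
#'   `list(synthetic = list(...))` of [synthetic_spec()] arguments.
#' @param qc Named list of [qc_thresholds()] overrides.
#' @param background_sd_multiplier Background SD multiplier.
#' @param genorm_k Number of references to select.
#' @param use_positives Apply positive-control normalization first.
#' @param comparisons List of 2-vectors of diagnosis groups (default:
#'   all three pairwise comparisons).
#' @param alpha Significance level for the adjusted p-values.
#' @param cluster_k_range Candidate cluster numbers.
#' @param classifier Named list: `positive`, `folds`, `lambda`
#'   (optional fixed penalty), `corr_cutoff`.
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, qc = list(),
                            background_sd_multiplier = 2,
                            genorm_k = 3L, use_positives = TRUE,
                            comparisons = list(
                              c("AMR", "NoRejection"),
                              c("AMR", "BLorTCMR"),
                              c("BLorTCMR", "NoRejection")),
                            alpha = 0.05,
                            cluster_k_range = 2:10,
                            classifier = list(),
                            seed = 1L, out_dir = NULL) {
  stopifnot(is.list(input),
            !is.null(input$dir) || !is.null(input$synthetic))
  classifier <- utils::modifyList(
    list(positive = "AMR", folds = 10L, lambda = NULL,
         corr_cutoff = 0.9), classifier)
  for (cmp in comparisons)
    stopifnot(length(cmp) == 2L, all(cmp %in% diagnosis_levels()))
  structure(list(
    input = input, qc = qc,
    background_sd_multiplier = background_sd_multiplier,
    genorm_k = as.integer(genorm_k), use_positives = use_positives,
    comparisons = comparisons, alpha = alpha,
    cluster_k_range = cluster_k_range, classifier = classifier,
    seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

write_stage_csv <- function(df, dir, name) {
  if (!is.null(dir))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

write_stage_json <- function(x, dir, name) {
  if (!is.null(dir))
    jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Executes ingest/simulate, lane QC, background probe filtering,
#' geNorm-based normalization, pairwise differential expression,
#' clustering diagnostics and classifier training/evaluation in fixed
#' order. When `out_dir` is set, every stage's tables are persisted as
#' CSV/JSON and a run manifest records the seed, a hash of the
#' configuration, package version, and per-stage sample/probe attrition.
#' Reruns with the same configuration and seed reproduce all outputs
#' bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @return A list with each stage's results plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE,
                                recursive = TRUE)
  seed <- config$seed

  # --- ingest -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input$synthetic)) {
    args <- config$input$synthetic
    args$seed <- args$seed %||% stage_seed(seed, "simulate")
    spec <- do.call(synthetic_spec, args)
    ds <- generate_dataset(spec)
    truth <- ds$truth
    mat <- assemble_matrix(ds$lanes, ds$panel, ds$samples)
  } else {
    mat <- read_dataset(config$input$dir)
  }
  n_in <- ncol(mat$values)

  # --- lane QC ------------------------------------------------------
  th <- do.call(qc_thresholds, config$qc)
  report <- lane_qc(mat, thresholds = th)
  write_stage_csv(report, dir, "qc_report.csv")
  passed <- filter_samples(mat, report)
  n_pass <- ncol(passed$values)

  # --- background filter --------------------------------------------
  bg <- apply_probe_filter(passed,
                           sd_multiplier = config$background_sd_multiplier)
  if (!is.null(dir)) {
    write_stage_csv(data.frame(
      sample_id = names(bg$per_sample_background),
      background = unname(bg$per_sample_background)), dir,
      "background_per_sample.csv")
    write_stage_json(list(study_threshold = bg$study_threshold,
                          excluded_probes = bg$excluded_probes,
                          flagged_housekeeping = bg$flagged_housekeeping),
                     dir, "background.json")
  }

  # --- normalization ------------------------------------------------
  nres <- normalize_matrix(bg$kept_matrix, k = config$genorm_k,
                           use_positives = config$use_positives)
  norm <- nres$norm
  if (!is.null(dir)) {
    write_stage_csv(data.frame(
      gene = names(nres$genorm$stability_M),
      stability_M = unname(nres$genorm$stability_M),
      initial_M = unname(nres$genorm$initial_M[
        names(nres$genorm$stability_M)]),
      selected = names(nres$genorm$stability_M) %in%
        nres$genorm$selected_references), dir, "genorm.csv")
    utils::write.csv(data.frame(probe_id = rownames(norm$values),
                                norm$values, check.names = FALSE),
                     file.path(dir, "normalized.csv"), row.names = FALSE)
  }

  # --- differential expression --------------------------------------
  dge <- list()
  for (cmp in config$comparisons) {
    key <- paste(cmp, collapse = "_vs_")
    tab <- dge_table(norm, cmp[1], cmp[2], alpha = config$alpha)
    dge[[key]] <- tab
    write_stage_csv(tab, dir, paste0("dge_", key, ".csv"))
    write_stage_csv(volcano_data(tab), dir,
                    paste0("volcano_", key, ".csv"))
  }

  # --- clustering diagnostics ---------------------------------------
  clust <- cluster_diagnostics(norm, k_range = config$cluster_k_range,
                               seed = stage_seed(seed, "cluster"))
  write_stage_json(list(hopkins_H = clust$hopkins_H,
                        cophenetic_r = clust$cophenetic_r,
                        c_index_by_k = as.list(clust$c_index_by_k),
                        optimal_k = clust$optimal_k),
                   dir, "cluster.json")

  # --- classifier ---------------------------------------------------
  cl <- config$classifier
  model <- train_classifier(norm, positive = cl$positive,
                            folds = cl$folds,
                            seed = stage_seed(seed, "classifier"),
                            lambda = cl$lambda,
                            corr_cutoff = cl$corr_cutoff)
  eval <- cv_evaluate(model$X, model$y, lambda = model$lambda,
                      folds = cl$folds,
                      seed = stage_seed(seed, "classifier"))
  if (!is.null(dir)) {
    write_stage_json(list(
      panel = model$panel_name, positive = model$positive,
      lambda = model$lambda,
      genes = as.list(model$coefficients),
      intercept = model$intercept,
      standardization = list(
        center = as.list(model$preprocessing$center[
          names(model$coefficients)]),
        scale = as.list(model$preprocessing$scale[
          names(model$coefficients)])),
      nzv_removed = model$preprocessing$nzv_removed,
      corr_removed = model$preprocessing$corr_removed),
      dir, "model.json")
    write_stage_json(list(auc = eval$auc,
                          sensitivity = eval$sensitivity,
                          specificity = eval$specificity,
                          threshold = eval$threshold,
                          confusion = as.vector(eval$confusion),
                          youden = eval$youden),
                     dir, "eval.json")
  }

  # --- manifest -----------------------------------------------------
  config_json <- jsonlite::toJSON(
    config[setdiff(names(config), "out_dir")],
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  tmp <- tempfile(); writeLines(config_json, tmp)
  config_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  n_probes_in <- nrow(mat$values)
  manifest <- list(
    package_version = as.character(utils::packageVersion("nanoreject")),
    seed = seed,
    config_hash = config_hash,
    attrition = list(
      samples_in = n_in,
      samples_excluded_qc = n_in - n_pass,
      samples_out = n_pass,
      probes_in = n_probes_in,
      probes_excluded_background = length(bg$excluded_probes),
      probes_out = nrow(bg$kept_matrix$values)
    )
  )
  write_stage_json(manifest, dir, "manifest.json")

  invisible(list(raw = mat, qc_report = report, qc_passed = passed,
                 background = bg, normalization = nres, norm = norm,
                 dge = dge, cluster = clust, model = model,
                 evaluation = eval, manifest = manifest, truth = truth))
}
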