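#' Near-zero-variance gene filter
#'
#' A gene is removed when the frequency ratio of its most common to its
#' second most common value exceeds `freq_cut` and the percentage of
#' distinct values is below `unique_cut` (constant genes always fail).
#' Delegates to the standard caret rule.
#'
#' @param values Genes x samples matrix.
#' @param freq_cut Frequency-ratio threshold (default 95/5 = 19).
#' @param unique_cut Distinct-value percentage threshold (default 10).
#' @return List with `kept` and `removed` gene names.
#' @export
near_zero_variance_filter <- function(values, freq_cut = 19,
                                      unique_cut = 10) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  removed_idx <- caret::nearZeroVar(t(values), freqCut = freq_cut,
                                    uniqueCut = unique_cut)
  removed <- rownames(values)[removed_idx]
  list(kept = setdiff(rownames(values), removed), removed = removed)
}

#' High-correlation gene filter
#'
#' Greedy removal: while any gene pair has absolute Pearson correlation
#' above `cutoff`, the member with the larger mean absolute correlation
#' to all remaining genes is removed. Genes are processed in
#' lexicographic order so ties resolve deterministically.
#'
#' @param values Genes x samples matrix (run the near-zero-variance
#'   filter first; constant genes have undefined correlations).
#' @param cutoff Absolute-correlation threshold (default 0.9).
#' @return List with `kept` and `removed` gene names.
#' @export
correlation_filter <- function(values, cutoff = 0.9) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  values <- values[sort(rownames(values)), , drop = FALSE]
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s) present; apply near_zero_variance_filter first: ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  cm <- stats::cor(t(values))
  removed <- caret::findCorrelation(cm, cutoff = cutoff, exact = TRUE,
                                    names = TRUE)
  list(kept = setdiff(rownames(values), removed), removed = removed)
}

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  if (any(scale == 0))
    stop("cannot standardize constant predictor(s): ",
         paste(utils::head(colnames(X)[scale == 0], 5), collapse = ", "))
  list(center = center, scale = scale,
       X = sweep(sweep(X, 2, center), 2, scale, `/`))
}

standardize_apply <- function(X, center, scale) {
  sweep(sweep(X, 2, center[colnames(X)]), 2, scale[colnames(X)], `/`)
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds)
      stop("class ", cls, " has fewer samples than folds")
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

#' Fit an L1-penalized logistic classifier with cross-validated lambda
#'
#' Minimizes the mean logistic deviance plus `lambda * sum(|beta|)` over
#' a lambda grid; lambda is chosen by stratified 10-fold cross-validation
#' at the minimum mean held-out deviance, then the model is refit on all
#' samples. Predictors are standardized (mean 0, SD 1) with the
#' standardization parameters frozen into the model; inside each
#' cross-validation fold standardization is recomputed on the training
#' part only. A fixed `lambda` bypasses the cross-validation (e.g. to
#' replay a previously determined penalty).
#'
#' @param X Samples x genes matrix, columns named by gene.
#' @param y Binary response (1 = positive class).
#' @param lambda_grid Optional decreasing lambda sequence (defaults to
#'   the glmnet path).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @param lambda Optional fixed penalty overriding CV selection.
#' @return A `classifier_model`: frozen standardization, chosen
#'   `lambda`, nonzero `coefficients` (standardized units) and
#'   `coefficients_raw` (original units), `intercept`, and the CV
#'   deviance curve.
#' @export
fit_lasso <- function(X, y, lambda_grid = NULL, folds = 10L, seed = 1L,
                      lambda = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("response has a single class")
  if (nrow(X) < folds) stop("fewer samples than folds")
  std <- standardize_fit(X)

  if (is.null(lambda_grid)) {
    path <- glmnet::glmnet(std$X, y, family = "binomial", alpha = 1,
                           standardize = FALSE)
    lambda_grid <- path$lambda
  }
  cv_table <- NULL
  if (is.null(lambda)) {
    fold_id <- stratified_folds(y, folds, seed)
    dev <- matrix(NA_real_, nrow = folds, ncol = length(lambda_grid))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      std_tr <- standardize_fit(X[tr, , drop = FALSE])
      fit <- glmnet::glmnet(std_tr$X, y[tr], family = "binomial",
                            alpha = 1, standardize = FALSE,
                            lambda = lambda_grid)
      Xte <- standardize_apply(X[!tr, , drop = FALSE], std_tr$center,
                               std_tr$scale)
      p <- stats::predict(fit, Xte, s = lambda_grid, type = "response")
      dev[f, ] <- apply(p, 2, function(pp) binomial_deviance(y[!tr], pp))
    }
    mean_dev <- colMeans(dev)
    lambda <- lambda_grid[which.min(mean_dev)]
    cv_table <- data.frame(lambda = lambda_grid, mean_deviance = mean_dev)
  }

  final <- glmnet::glmnet(std$X, y, family = "binomial", alpha = 1,
                          standardize = FALSE,
                          lambda = sort(unique(c(lambda_grid, lambda)),
                                        decreasing = TRUE))
  beta <- stats::coef(final, s = lambda, exact = TRUE, x = std$X, y = y,
                      family = "binomial", alpha = 1,
                      standardize = FALSE)
  beta <- as.numeric(beta)
  names(beta) <- c("(Intercept)", colnames(X))
  nz <- beta[-1][beta[-1] != 0]
  coef_raw <- nz / std$scale[names(nz)]
  intercept_raw <- beta[1] - sum(coef_raw * std$center[names(nz)])

  structure(list(
    genes = colnames(X),
    preprocessing = list(center = std$center, scale = std$scale),
    lambda = lambda,
    coefficients = nz,
    intercept = unname(beta[1]),
    coefficients_raw = coef_raw,
    intercept_raw = unname(intercept_raw),
    cv = cv_table,
    cv_spec = list(folds = folds, seed = seed)),
    class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf(
    "L1 logistic model: lambda = %.4g, %d nonzero gene(s) of %d\n",
    x$lambda, length(x$coefficients), length(x$genes)))
  invisible(x)
}

#' Predict class probabilities from a fitted model
#'
#' Applies the model's frozen standardization and coefficients.
#'
#' @param object A `classifier_model`.
#' @param newdata Samples x genes matrix containing at least the model's
#'   coefficient genes (by column name).
#' @param ... Unused.
#' @return Per-sample probability of the positive class.
#' @export
predict.classifier_model <- function(object, newdata, ...) {
  genes <- names(object$coefficients)
  missing <- setdiff(genes, colnames(newdata))
  if (length(missing) > 0L)
    stop("model gene(s) absent from target data: ",
         paste(missing, collapse = ", "))
  Xs <- standardize_apply(newdata[, genes, drop = FALSE],
                          object$preprocessing$center,
                          object$preprocessing$scale)
  as.numeric(stats::plogis(object$intercept +
                             Xs %*% object$coefficients))
}

#' ROC curve, AUC and operating characteristics
#'
#' ROC points from a threshold sweep over the predicted probabilities,
#' AUC by the trapezoidal rule, and sensitivity / specificity with the
#' confusion matrix at a probability threshold (default 0.5), with the
#' Youden-optimal threshold reported alongside.
#'
#' @param probs Predicted probabilities of the positive class.
#' @param y Binary labels (1 = positive).
#' @param threshold Operating threshold (default 0.5).
#' @return An `eval_result` list: `roc_points` (FPR, TPR), `auc`,
#'   `threshold`, `sensitivity`, `specificity`, `confusion` (2x2),
#'   `youden` (threshold, sensitivity, specificity).
#' @export
eval_result <- function(probs, y, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(length(probs) == length(y), all(y %in% 0:1))
  pos <- sum(y == 1); neg <- sum(y == 0)
  if (pos == 0L || neg == 0L) stop("both classes required for evaluation")
  ord <- order(probs, decreasing = TRUE)
  ys <- y[ord]; ps <- probs[ord]
  # group tied probabilities
  grp <- cumsum(!duplicated(ps))
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / pos)
  fpr <- c(0, fp[last] / neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  conf_at <- function(thr) {
    pred <- as.integer(probs >= thr)
    tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
    tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
    list(confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                            dimnames = list(predicted = c("pos", "neg"),
                                            truth = c("pos", "neg"))),
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  }
  at <- conf_at(threshold)
  cand <- sort(unique(c(0, probs, 1)))
  youden_scores <- vapply(cand, function(t) {
    cc <- conf_at(t); cc$sensitivity + cc$specificity - 1
  }, 1.0)
  yt <- cand[which.max(youden_scores)]
  yc <- conf_at(yt)
  structure(list(
    roc_points = data.frame(fpr = fpr, tpr = tpr),
    auc = auc, threshold = threshold,
    sensitivity = at$sensitivity, specificity = at$specificity,
    confusion = at$confusion,
    youden = list(threshold = yt, sensitivity = yc$sensitivity,
                  specificity = yc$specificity),
    probs = probs, labels = y), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f; at threshold %.2f: sensitivity %.3f, specificity %.3f\n",
    x$auc, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Cross-validated evaluation with pooled out-of-fold predictions
#'
#' Stratified k-fold cross-validation in which standardization and the
#' penalized fit are redone inside each training fold at the supplied
#' penalty; the held-out probabilities are pooled over folds and
#' summarized with [eval_result()].
#'
#' @param X Samples x genes matrix (post-filtering).
#' @param y Binary labels.
#' @param lambda Penalty to use inside each fold (e.g. from
#'   [fit_lasso()]).
#' @param folds Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @param threshold Operating threshold for the report.
#' @return An `eval_result`.
#' @export
cv_evaluate <- function(X, y, lambda, folds = 10L, seed = 1L,
                        threshold = 0.5) {
  X <- as.matrix(X); y <- as.integer(y)
  fold_id <- stratified_folds(y, folds, seed)
  probs <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    std_tr <- standardize_fit(X[tr, , drop = FALSE])
    fit <- glmnet::glmnet(std_tr$X, y[tr], family = "binomial",
                          alpha = 1, standardize = FALSE)
    Xte <- standardize_apply(X[!tr, , drop = FALSE], std_tr$center,
                             std_tr$scale)
    probs[!tr] <- as.numeric(stats::predict(
      fit, Xte, s = lambda, type = "response", exact = TRUE,
      x = std_tr$X, y = y[tr], family = "binomial", alpha = 1,
      standardize = FALSE))
  }
  eval_result(probs, y, threshold)
}

#' Apply a fitted model to another panel's data
#'
#' Maps the model's coefficient genes into the target panel by gene
#' symbol (probe IDs may differ between panels), applies the frozen
#' standardization and coefficients, and evaluates against the supplied
#' labels.
#'
#' @param model A `classifier_model`.
#' @param other_X Samples x genes matrix from the target panel, columns
#'   named by gene symbol.
#' @param y Binary labels for the target samples.
#' @param threshold Operating threshold.
#' @return An `eval_result` with a `gene_mapping` attribute.
#' @export
transfer_evaluate <- function(model, other_X, y, threshold = 0.5) {
  probs <- predict(model, other_X)
  out <- eval_result(probs, y, threshold)
  attr(out, "gene_mapping") <- names(model$coefficients)
  out
}

#' Train the AMR classifier from a normalized matrix
#'
#' End-to-end model building on a normalized expression matrix:
#' log2(x + 1) transform of the endogenous probes, near-zero-variance
#' and correlation filters, then the penalized fit of AMR versus the
#' pooled remaining diagnoses.
#'
#' @param norm A `content_normalized` [count_matrix()].
#' @param positive Positive diagnosis class (default `"AMR"`).
#' @param folds,seed,lambda Passed to [fit_lasso()].
#' @param corr_cutoff Correlation-filter threshold.
#' @return A `classifier_model` with `nzv_removed` / `corr_removed`
#'   recorded in `preprocessing` and the design matrix attached for
#'   evaluation (`X`, `y`).
#' @export
train_classifier <- function(norm, positive = "AMR", folds = 10L,
                             seed = 1L, lambda = NULL,
                             corr_cutoff = 0.9) {
  stopifnot(inherits(norm, "count_matrix"))
  ids <- matrix_rows(norm, "Endogenous")
  values <- log2(norm$values[ids, , drop = FALSE] + 1)
  rownames(values) <- norm$panel$probes$gene_symbol[
    match(ids, norm$panel$probes$probe_id)]
  nzv <- near_zero_variance_filter(values)
  values <- values[nzv$kept, , drop = FALSE]
  cf <- correlation_filter(values, cutoff = corr_cutoff)
  values <- values[cf$kept, , drop = FALSE]
  y <- as.integer(norm$samples$diagnosis == positive)
  X <- t(values)
  model <- fit_lasso(X, y, folds = folds, seed = seed, lambda = lambda)
  model$panel_name <- norm$panel$name
  model$positive <- positive
  model$preprocessing$nzv_removed <- nzv$removed
  model$preprocessing$corr_removed <- cf$removed
  model$X <- X
  model$y <- y
  model
}

#' Extract the classifier design matrix from another panel
#'
#' Builds the samples x genes log2(x + 1) matrix of a normalized
#' matrix's endogenous probes, columns named by gene symbol, for use
#' with [predict.classifier_model()] / [transfer_evaluate()].
#'
#' @param norm A `content_normalized` [count_matrix()].
#' @return Samples x genes matrix.
#' @export
classifier_design <- function(norm) {
  ids <- matrix_rows(norm, "Endogenous")
  values <- log2(norm$values[ids, , drop = FALSE] + 1)
  rownames(values) <- norm$panel$probes$gene_symbol[
    match(ids, norm$panel$probes$probe_id)]
  t(values)
}
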