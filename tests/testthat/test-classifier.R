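test_that("near-zero-variance rule removes degenerate genes only", {
  n <- 40
  values <- rbind(
    const = rep(3, n),
    spike = c(rep(5, 39), 9),            # ratio 39 > 19, distinct 2/40
    rising = seq_len(n),                 # strictly increasing
    almost = c(rep(1, 30), 2:11))        # ratio 30/1 > 19 but 11/40 unique
  res <- near_zero_variance_filter(values)
  expect_true(all(c("const", "spike") %in% res$removed))
  expect_true(all(c("rising", "almost") %in% res$kept))
})

test_that("correlation filter removes one of each collinear set", {
  set.seed(61)
  base <- stats::rnorm(30)
  values <- rbind(
    a_dup1 = base, a_dup2 = base,
    b1 = base * 2 + stats::rnorm(30, 0, 1e-8),
    ind1 = stats::rnorm(30), ind2 = stats::rnorm(30))
  res <- correlation_filter(values, cutoff = 0.9)
  # three mutually collinear genes -> exactly two removed
  trio <- c("a_dup1", "a_dup2", "b1")
  expect_length(intersect(res$removed, trio), 2L)
  expect_true(all(c("ind1", "ind2") %in% res$kept))
  # pairwise-independent random genes: nothing removed
  indep <- matrix(stats::rnorm(20 * 50), nrow = 20,
                  dimnames = list(sprintf("g%02d", 1:20), NULL))
  expect_length(correlation_filter(indep, cutoff = 0.9)$removed, 0L)
  # constant gene -> instructive error
  expect_error(correlation_filter(rbind(values, flat = rep(1, 30))),
               "constant")
})

test_that("infinite penalty shrinks to the intercept-only model", {
  set.seed(71)
  X <- matrix(stats::rnorm(60 * 10), nrow = 60,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  y <- rep(c(1, 0), c(20, 40))
  model <- fit_lasso(X, y, lambda = 1e6)
  expect_length(model$coefficients, 0L)
  prev <- mean(y)
  expect_equal(model$intercept, log(prev / (1 - prev)), tolerance = 1e-4)
})

test_that("a perfectly separating gene dominates the fit", {
  set.seed(72)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  X <- matrix(stats::rnorm(n * 20), nrow = n,
              dimnames = list(NULL, sprintf("g%02d", 1:20)))
  X[, "g01"] <- y * 4 + stats::rnorm(n, 0, 0.1)
  model <- fit_lasso(X, y, lambda = 0.05)
  expect_true("g01" %in% names(model$coefficients))
  expect_identical(names(which.max(abs(model$coefficients))), "g01")
})

test_that("a fixed lambda override is honored and recorded", {
  set.seed(73)
  X <- matrix(stats::rnorm(50 * 8), nrow = 50,
              dimnames = list(NULL, sprintf("g%d", 1:8)))
  y <- rep(0:1, 25)
  model <- fit_lasso(X, y, lambda = 0.034)
  expect_equal(model$lambda, 0.034)
  expect_null(model$cv)
})

test_that("fit_lasso enforces its preconditions", {
  X <- matrix(stats::rnorm(40), nrow = 8,
              dimnames = list(NULL, paste0("g", 1:5)))
  expect_error(fit_lasso(X, rep(1, 8)), "single class")
  expect_error(fit_lasso(X, rep(0:1, 4), folds = 10), "fewer samples")
})

test_that("raw-unit coefficients reproduce the standardized predictions", {
  set.seed(74)
  X <- matrix(stats::rnorm(80 * 12, mean = 7, sd = 3), nrow = 80,
              dimnames = list(NULL, sprintf("g%02d", 1:12)))
  y <- as.integer(X[, 1] + stats::rnorm(80) > 7)
  model <- fit_lasso(X, y, lambda = 0.02)
  p_std <- predict(model, X)
  eta_raw <- model$intercept_raw +
    X[, names(model$coefficients_raw), drop = FALSE] %*%
      model$coefficients_raw
  expect_equal(p_std, as.numeric(stats::plogis(eta_raw)),
               tolerance = 1e-10)
})

test_that("ROC/AUC agree with the rank-statistic and pROC oracles", {
  set.seed(75)
  y <- rep(c(0, 1), each = 30)
  probs <- stats::plogis(stats::rnorm(60) + y)
  ev <- eval_result(probs, y)
  # Mann-Whitney U normalization on the same probabilities
  u <- sum(rank(probs)[y == 1]) - sum(y) * (sum(y) + 1) / 2
  auc_u <- u / (sum(y) * sum(1 - y))
  expect_equal(ev$auc, auc_u, tolerance = 1e-12)
  expect_equal(ev$auc,
               as.numeric(pROC::auc(pROC::roc(y, probs, quiet = TRUE))),
               tolerance = 1e-9)
  # confusion accounting
  expect_equal(sum(ev$confusion), 60)
  expect_equal(colSums(ev$confusion), c(pos = 30, neg = 30))
  # oracle feature
  ev2 <- eval_result(y * 0.9 + 0.05, y)
  expect_equal(ev2$auc, 1)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 1)
})

test_that("cross-validation holds each fold out of its own training", {
  set.seed(76)
  n <- 40
  X <- matrix(stats::rnorm(n * 6), nrow = n,
              dimnames = list(NULL, paste0("g", 1:6)))
  y <- rep(0:1, each = n / 2)
  fold_id <- stratified_folds(y, 5L, seed = 9)
  tr <- fold_id != 1L
  fit_orig <- {
    std <- standardize_fit(X[tr, , drop = FALSE])
    glmnet::glmnet(std$X, y[tr], family = "binomial", alpha = 1,
                   standardize = FALSE, lambda = 0.05)
  }
  X_leak <- X
  X_leak[!tr, ] <- 1e6  # corrupt only the held-out fold
  fit_leak <- {
    std <- standardize_fit(X_leak[tr, , drop = FALSE])
    glmnet::glmnet(std$X, y[tr], family = "binomial", alpha = 1,
                   standardize = FALSE, lambda = 0.05)
  }
  expect_equal(as.numeric(fit_orig$beta), as.numeric(fit_leak$beta))
  # pooled out-of-fold evaluation runs and is seeded-reproducible
  e1 <- cv_evaluate(X, y, lambda = 0.05, folds = 5, seed = 9)
  e2 <- cv_evaluate(X, y, lambda = 0.05, folds = 5, seed = 9)
  expect_identical(e1$probs, e2$probs)
  expect_error(cv_evaluate(X, y, lambda = 0.05, folds = 25, seed = 1),
               "fewer samples")
})

test_that("transfer applies frozen standardization across panels", {
  spec <- synthetic_spec_fast(seed = 81)
  pair <- generate_paired_dataset(spec, n_sub_endogenous = 30L,
                                  n_sub_housekeeping = 3L)
  prep <- function(ds) {
    mat <- assemble_matrix(ds$lanes, ds$panel, ds$samples)
    normalize_matrix(apply_probe_filter(mat)$kept_matrix)$norm
  }
  norm_small <- prep(pair$small)
  norm_large <- prep(pair$large)
  model <- train_classifier(norm_small, seed = 82, lambda = 0.05)
  # applied to its own training matrix: identical to in-sample scoring
  own <- transfer_evaluate(model, model$X, model$y)
  expect_equal(own$probs, predict(model, model$X))
  # cross-panel mapping by gene symbol succeeds
  X_large <- classifier_design(norm_large)
  y <- as.integer(norm_large$samples$diagnosis == "AMR")
  ev <- transfer_evaluate(model, X_large, y)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  # a coefficient gene absent from the target panel is named
  missing_gene <- names(model$coefficients)[1]
  X_missing <- X_large[, colnames(X_large) != missing_gene, drop = FALSE]
  expect_error(transfer_evaluate(model, X_missing, y), missing_gene)
})
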