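test_that("perfectly co-regulated candidates all get M = 0", {
  base <- c(2, 5, 9, 4, 7, 1, 8, 3, 6, 10, 12, 11) * 10
  values <- rbind(g1 = base, g2 = base * 2, g3 = base * 0.5)
  res <- genorm_rank(values, k = 2)
  expect_equal(unname(res$stability_M), rep(0, 3))
  expect_equal(unname(res$initial_M), rep(0, 3))
})

test_that("geNorm matches the brute-force oracle on random matrices", {
  set.seed(404)
  for (rep in 1:10) {
    g <- sample(6:10, 1); s <- sample(8:15, 1)
    values <- matrix(2^stats::runif(g * s, 3, 11), nrow = g,
                     dimnames = list(sprintf("g%02d", seq_len(g)), NULL))
    res <- genorm_rank(values, k = 3)
    oracle <- genorm_oracle(values)
    expect_equal(res$stability_M, oracle$stability_M, tolerance = 1e-9)
    expect_identical(res$elimination_order, oracle$elimination_order)
  }
})

test_that("geNorm is invariant to positive per-sample column scaling", {
  set.seed(7)
  values <- matrix(2^stats::runif(60, 4, 10), nrow = 6,
                   dimnames = list(sprintf("g%d", 1:6), NULL))
  scaled <- sweep(values, 2, stats::runif(10, 0.2, 5), `*`)
  r1 <- genorm_rank(values, k = 3)
  r2 <- genorm_rank(scaled, k = 3)
  expect_equal(r1$stability_M, r2$stability_M, tolerance = 1e-12)
  expect_identical(r1$elimination_order, r2$elimination_order)
})

test_that("stable synthetic tiers are recovered as selected references", {
  spec <- synthetic_spec_fast(
    housekeeping_cv_tiers = c(0.05, 0.05, 0.05, 0.3, 0.45, 0.6),
    seed = 17)
  ds <- generate_dataset(spec)
  mat <- assemble_matrix(ds$lanes, ds$panel, ds$samples)
  res <- normalize_matrix(mat, k = 3)
  stable <- names(sort(ds$truth$reference_cv))[1:3]
  expect_setequal(res$genorm$selected_references, stable)
})

test_that("candidate preconditions and pseudocount handling", {
  values <- matrix(c(1, 2, 4, 2, 4, 8), nrow = 2,
                   dimnames = list(c("a", "b"), NULL))
  expect_error(genorm_rank(values), "at least 3")
  v3 <- rbind(values, c = c(3, 0, 5))
  expect_error(genorm_rank(v3, k = 2, pseudocount = NULL), "pseudocount")
  res <- genorm_rank(v3, k = 2)  # pseudocount path must run
  expect_true(all(is.finite(res$stability_M)))
  # the V(m/m+1) series is reported for every m from 2 to g-1
  set.seed(1)
  v6 <- matrix(2^stats::runif(48, 4, 9), nrow = 6,
               dimnames = list(letters[1:6], NULL))
  expect_named(genorm_rank(v6, k = 3)$vk,
               c("V2/3", "V3/4", "V4/5", "V5/6"))
})

test_that("content factors follow the cohort-anchor arithmetic", {
  panel <- toy_panel(n_hk = 2L)
  lanes <- list(toy_lane(panel, "A", hk = 100),
                toy_lane(panel, "B", hk = 400))
  meta <- data.frame(sample_id = c("A", "B"),
                     diagnosis = c("AMR", "NoRejection"), center = "X",
                     stringsAsFactors = FALSE)
  mat <- assemble_matrix(lanes, panel, meta)
  norm <- content_normalize(mat, c("HK01", "HK02"))
  # reference geomeans (100, 400) -> factors (2.5, 0.625)
  expect_equal(unname(attr(norm, "content_factors")), c(2.5, 0.625))
  # identical reference counts -> all factors 1, matrix unchanged
  mat2 <- assemble_matrix(list(toy_lane(panel, "A"), toy_lane(panel, "B")),
                          panel, meta)
  norm2 <- content_normalize(mat2, c("HK01", "HK02"))
  expect_equal(unname(attr(norm2, "content_factors")), c(1, 1))
  expect_equal(norm2$values, mat2$values)
})

test_that("after content normalization the reference geomean is constant", {
  spec <- synthetic_spec_fast(seed = 8)
  ds <- generate_dataset(spec)
  mat <- assemble_matrix(ds$lanes, ds$panel, ds$samples)
  res <- normalize_matrix(mat, k = 3)
  gm <- apply(res$norm$values[res$references, , drop = FALSE], 2,
              function(x) exp(mean(log(x))))
  expect_equal(unname(gm), rep(gm[[1]], length(gm)), tolerance = 1e-12)
})

test_that("doubling a column rescales the cohort uniformly, never that sample alone", {
  spec <- synthetic_spec_fast(seed = 12)
  ds <- generate_dataset(spec)
  mat <- assemble_matrix(ds$lanes, ds$panel, ds$samples)
  res1 <- normalize_matrix(mat, k = 3)
  doubled <- mat
  doubled$values[, 4] <- 2 * doubled$values[, 4]
  res2 <- normalize_matrix(doubled, k = 3)
  expect_identical(res2$genorm$selected_references,
                   res1$genorm$selected_references)
  pos <- res1$norm$values > 0
  ratio <- res2$norm$values[pos] / res1$norm$values[pos]
  # one global anchor rescaling shared by every entry of every sample:
  # the doubled sample's normalized profile is unchanged relative to all
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  expect_true(all(res2$norm$values[!pos] == 0))
})

test_that("missing references and zero geomeans error out", {
  mat <- background_toy_matrix()
  expect_error(content_normalize(mat, c("HK1", "NOPE")), "NOPE")
  mat$values["HK1", 1] <- 0
  expect_error(content_normalize(mat, c("HK1", "HK2")), "positive")
})
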