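test_that("median log2 fold change uses group medians with zero-guard", {
  values <- rbind(
    g1 = c(8, 8, 8, 2, 2, 2),
    g2 = c(5, 5, 5, 5, 5, 5),
    g3 = c(0, 0, 0, 3, 3, 3))
  grp <- rep(c("A", "B"), each = 3)
  lfc <- median_log2fc(values, grp, "A", "B")
  expect_equal(unname(lfc["g1"]), 2)
  expect_equal(unname(lfc["g2"]), 0)
  # medians 0 vs 3 with pseudocount 0.5 on both -> log2(0.5/3.5)
  expect_equal(unname(lfc["g3"]), log2(0.5 / 3.5), tolerance = 1e-12)
  expect_equal(unname(lfc["g3"]), -2.8074, tolerance = 1e-4)
  expect_error(median_log2fc(values, grp, "A", "C"), "empty group")
})

test_that("Wilcoxon p-values: exact enumeration and degenerate cases", {
  values <- rbind(
    sep = c(1, 2, 3, 10, 11, 12),
    same = c(4, 4, 4, 4, 4, 4))
  grp <- rep(c("A", "B"), each = 3)
  p <- wilcoxon_de(values, grp, "A", "B")
  # complete separation at n = 3/3: 2 / choose(6, 3) = 0.1 two-sided
  expect_equal(unname(p["sep"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(p["same"]), 1)
  # identical groups -> p = 1 for every gene
  values2 <- matrix(rep(c(3, 1, 4, 1, 5, 9), each = 2), nrow = 2,
                    byrow = FALSE,
                    dimnames = list(c("x", "y"), NULL))
  values2 <- cbind(values2, values2)
  p2 <- wilcoxon_de(values2, rep(c("A", "B"), each = 6), "A", "B")
  expect_true(all(p2 == 1))
})

test_that("Wilcoxon is invariant to monotone transforms", {
  set.seed(11)
  values <- matrix(stats::rexp(20 * 12), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
  grp <- rep(c("A", "B"), each = 6)
  p1 <- wilcoxon_de(values, grp, "A", "B")
  p2 <- wilcoxon_de(log1p(values)^3, grp, "A", "B")
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Benjamini-Yekutieli adjustment follows the step-up formula", {
  expect_equal(adjust_by(0.2), 0.2)
  # m = 2, c(2) = 1.5: (0.01, 0.04) -> (0.03, 0.06)
  expect_equal(adjust_by(c(0.01, 0.04)), c(0.03, 0.06),
               tolerance = 1e-12)
  set.seed(3)
  p <- stats::runif(200)
  by <- adjust_by(p)
  bh <- stats::p.adjust(p, method = "BH")
  expect_true(all(by >= bh - 1e-15) && all(bh >= p - 1e-15))
  expect_true(all(by <= 1))
  # monotone: smaller raw p never gets the larger adjusted p
  ord <- order(p)
  expect_true(!is.unsorted(by[ord]))
})

test_that("dge_table sorts by adjusted p and flags significance", {
  spec <- synthetic_spec_fast(seed = 23)
  ds <- generate_dataset(spec)
  mat <- assemble_matrix(ds$lanes, ds$panel, ds$samples)
  norm <- normalize_matrix(apply_probe_filter(mat)$kept_matrix)$norm
  tab <- dge_table(norm, "AMR", "NoRejection")
  expect_true(!is.unsorted(tab$fdr_p))
  expect_true(all(tab$fdr_p >= tab$p_raw - 1e-15))
  expect_identical(tab$significant, tab$fdr_p < 0.05)
  # planted effect genes dominate the top of the table
  truth <- names(ds$truth$de_genes$AMR_vs_NoRejection)
  expect_gte(length(intersect(top_degs(tab, 8), truth)), 6L)
})

test_that("top_degs breaks ties by absolute fold change then symbol", {
  tab <- data.frame(
    probe_id = paste0("p", 1:4), gene = c("D", "C", "B", "A"),
    median_a = 1, median_b = 1,
    log2fc = c(0.5, -2, 1, 1), p_raw = 0.01, fdr_p = 0.02,
    significant = TRUE, stringsAsFactors = FALSE)
  tab <- tab[order(tab$fdr_p, -abs(tab$log2fc), tab$gene), ]
  class(tab) <- c("dge_table", "data.frame")
  expect_identical(top_degs(tab, 2), c("C", "A"))
  expect_warning(got <- top_degs(tab, 10), "exceeds")
  expect_length(got, 4L)
})

test_that("retest correlation over top-list unions behaves at the poles", {
  set.seed(5)
  tab <- data.frame(
    probe_id = sprintf("p%02d", 1:30), gene = sprintf("G%02d", 1:30),
    median_a = 1, median_b = 1, log2fc = stats::rnorm(30),
    p_raw = stats::runif(30), stringsAsFactors = FALSE)
  tab$fdr_p <- adjust_by(tab$p_raw)
  tab <- tab[order(tab$fdr_p, -abs(tab$log2fc), tab$gene), ]
  class(tab) <- c("dge_table", "data.frame")
  expect_equal(retest_correlation(tab, tab), 1)
  neg <- tab; neg$log2fc <- -neg$log2fc
  expect_equal(retest_correlation(tab, neg), -1)
  expect_error(retest_correlation(tab, tab, shared_genes = "G01"),
               "fewer than 3")
})

test_that("panels sharing ground truth correlate on top-gene fold changes", {
  spec <- synthetic_spec(
    n_per_group = c(NoRejection = 30, BLorTCMR = 30, AMR = 30),
    n_endogenous = 300L, seed = 515)
  pair <- generate_paired_dataset(spec, n_sub_endogenous = 60L,
                                  n_sub_housekeeping = 6L)
  prep <- function(ds) {
    mat <- assemble_matrix(ds$lanes, ds$panel, ds$samples)
    normalize_matrix(apply_probe_filter(mat)$kept_matrix)$norm
  }
  ta <- dge_table(prep(pair$large), "AMR", "NoRejection")
  tb <- dge_table(prep(pair$small), "AMR", "NoRejection")
  expect_gt(retest_correlation(ta, tb, k = 20), 0.7)
})

test_that("volcano data mirrors the table axes", {
  tab <- data.frame(gene = c("a", "b"), log2fc = c(1, -2),
                    fdr_p = c(0.01, 1))
  v <- volcano_data(tab)
  expect_equal(v$neg_log10_fdr_p, c(2, 0))
})
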