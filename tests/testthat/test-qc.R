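test_that("positive-control linearity matches direct regression", {
  concs <- c(128, 32, 8, 2, 0.5, 0.125)
  # counts exactly proportional to concentration
  expect_equal(as.numeric(pos_control_linearity(concs * 150, concs)), 1)
  # exact power law: counts (1024, ..., 1) are 2^(10,8,6,4,2,0)
  r2 <- pos_control_linearity(c(1024, 256, 64, 16, 4, 1), concs)
  fit <- stats::lm(log2(c(1024, 256, 64, 16, 4, 1)) ~ log2(concs))
  expect_equal(as.numeric(r2),
               suppressWarnings(summary(fit)$r.squared),
               tolerance = 1e-12)
  expect_equal(as.numeric(r2), 1, tolerance = 1e-12)
  # degenerate flat titration
  flat <- pos_control_linearity(rep(7, 6), concs)
  expect_identical(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("limit of detection uses mean + 2 sample SDs of negatives", {
  # mean 8, sample SD 3.1623 -> threshold 14.3246
  expect_true(limit_of_detection(20, c(4, 6, 8, 10, 12)))
  expect_false(limit_of_detection(14, c(4, 6, 8, 10, 12)))
  expect_true(limit_of_detection(1, c(0, 0, 0, 0)))
  expect_false(limit_of_detection(9, c(10, 10, 10, 10)))
})

test_that("technical normalization factors anchor to the cohort mean", {
  panel <- toy_panel()
  pos <- c(1024, 256, 64, 16, 4, 1)
  lanes <- list(toy_lane(panel, "A", pos = pos),
                toy_lane(panel, "B", pos = pos * 2))
  meta <- data.frame(sample_id = c("A", "B"),
                     diagnosis = c("AMR", "NoRejection"), center = "X",
                     stringsAsFactors = FALSE)
  mat <- assemble_matrix(lanes, panel, meta)
  f <- technical_norm_factor(mat)
  # geomeans (g, 2g) -> factors (1.5, 0.75)
  expect_equal(unname(f), c(1.5, 0.75))
  # identical lanes -> all factors exactly 1
  mat2 <- assemble_matrix(list(toy_lane(panel, "A"), toy_lane(panel, "B")),
                          panel, meta)
  expect_equal(unname(technical_norm_factor(mat2)), c(1, 1))
  # scaling by the factors conserves the mean of per-sample geomeans
  g <- apply(mat$values[matrix_rows(mat, "Positive"), ], 2,
             function(x) exp(mean(log(x))))
  expect_equal(unname(f * g), rep(mean(g), 2))
})

test_that("the 12-lane fixture yields exactly the hand-computed exclusions", {
  mat <- qc_fixture()
  report <- lane_qc(mat)
  expect_setequal(report$sample_id[report$excluded],
                  qc_fixture_expected_excluded)
  # excluded <=> reasons nonempty
  expect_identical(report$excluded, nzchar(report$reasons))

  by_id <- function(id) report[report$sample_id == id, ]
  # binding-density exception: flagged but retained
  l03 <- by_id("L03")
  expect_false(l03$excluded)
  expect_match(l03$flags, "binding_density")
  expect_gt(l03$pos_r2, 0.95)
  l05 <- by_id("L05")
  expect_false(l05$excluded)
  expect_match(l05$flags, "binding_density")
  # flat positives alone: linearity flag, no exclusion
  l06 <- by_id("L06")
  expect_false(l06$excluded)
  expect_match(l06$flags, "pos_linearity")
  # reference geomean under 30 counts
  expect_match(by_id("L08")$reasons, "reference geomean")
  expect_equal(by_id("L08")$refgene_geomean, sqrt(25 * 25))
  # factor windows
  expect_gt(by_id("L09")$pos_norm_factor, 2)
  expect_gt(by_id("L10")$content_norm_factor, 8)
  # fully in-window lane: no flags at all
  expect_identical(by_id("L01")$flags, "")
})

test_that("lane QC decisions are invariant to sample order", {
  mat <- qc_fixture()
  perm <- c(7, 1, 12, 3, 9, 5, 2, 11, 4, 10, 8, 6)
  mat_perm <- subset_samples(mat, perm)
  r1 <- lane_qc(mat)
  r2 <- lane_qc(mat_perm)
  r2 <- r2[match(r1$sample_id, r2$sample_id), ]
  expect_equal(r1$excluded, r2$excluded)
  expect_equal(r1$pos_norm_factor, r2$pos_norm_factor)
})

test_that("a binding-density flag alone never excludes when the exception holds", {
  mat <- qc_fixture()
  report <- lane_qc(mat)
  bd_flagged <- grepl("binding_density", report$flags)
  ok <- report$pos_r2 > 0.95 &
    report$pos_norm_factor >= 0.1 & report$pos_norm_factor <= 2 &
    report$content_norm_factor >= 0.1 & report$content_norm_factor <= 8
  only_bd <- bd_flagged & ok & report$fov_ratio >= 0.75 & report$lod_pass &
    report$refgene_geomean >= 30
  expect_false(any(report$excluded[only_bd]))
})

test_that("filter_samples drops excluded columns and keeps order", {
  mat <- qc_fixture()
  report <- lane_qc(mat)
  kept <- filter_samples(mat, report)
  expect_identical(ncol(kept$values), 6L)
  expect_identical(colnames(kept$values),
                   setdiff(sprintf("L%02d", 1:12),
                           qc_fixture_expected_excluded))
  # no exclusions -> identity
  clean <- subset_samples(mat, mat$samples$sample_id %in%
                            c("L01", "L11", "L12"))
  rep2 <- lane_qc(clean)
  expect_false(any(rep2$excluded))
  expect_identical(filter_samples(clean, rep2)$values, clean$values)
  # all excluded -> empty-cohort error
  report_all <- report
  report_all$excluded <- TRUE
  expect_error(filter_samples(mat, report_all), "empty cohort")
})
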