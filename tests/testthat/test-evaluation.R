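test_that("the endpoint split reproduces the documented index arithmetic", {
  sp <- ma1_split(2644)
  expect_length(sp$external_test, 264L)
  sp <- ma1_split(100)
  expect_length(sp$external_test, 10L)
  expect_length(sp$internal_test, 9L)
  expect_length(sp$train, 81L)
  expect_error(ma1_split(12), "20 rows")
  # disjoint, exhaustive, external is the time-order suffix
  for (n in c(37, 100, 215, 2644)) {
    sp <- ma1_split(n)
    all_idx <- sort(c(sp$train, sp$internal_test, sp$external_test))
    expect_identical(all_idx, seq_len(n))
    expect_identical(sp$external_test, seq.int(n - n %/% 10L + 1L, n))
  }
})

test_that("the drying-phase split takes half the terminal zero-spray run", {
  b <- manual_batch(500, phase = rep(c("spray", "drying"), c(100, 400)))
  sp <- ma1add_split(b)
  expect_identical(sp$external_test, 301:500)
  expect_identical(sort(c(sp$train, sp$internal_test, sp$external_test)),
                   1:500)
  mid_spray <- manual_batch(60, phase = rep("spray", 60))
  expect_error(ma1add_split(mid_spray), "no zero-spray|mid-spray")
  ends_spraying <- manual_batch(
    60, phase = rep(c("spray", "drying", "spray"), c(30, 20, 10)))
  expect_error(ma1add_split(ends_spraying), "mid-spray")
})

test_that("across-batch folds partition the batch ids", {
  ids <- sprintf("b%02d", 1:12)
  f <- ma2_folds(ids, 9, 3)
  expect_length(f, 4L)
  expect_identical(unlist(lapply(f, `[[`, "test")), ids)
  for (fold in f) {
    expect_length(fold$train, 9L)
    expect_length(intersect(fold$train, fold$test), 0L)
  }
  f1 <- ma2_folds(ids, 11, 1)
  expect_length(f1, 12L)
  expect_error(ma2_folds(ids, 8, 3), "equal the")
  expect_error(ma2_folds(ids, 7, 5), "grouped")
})

test_that("block CV plans form contiguous near-equal partitions", {
  p <- block_cv_plan(100, 10)
  expect_identical(as.integer(table(p$fold)), rep(10L, 10))
  p <- block_cv_plan(101, 10)
  expect_identical(as.integer(table(p$fold)), c(11L, rep(10L, 9)))
  expect_false(is.unsorted(p$fold))
  expect_error(block_cv_plan(5, 6), "k must")
})

test_that("reference statistics match direct computation on pooled rows", {
  cmp <- tiny_campaign(4, rows = c(80, 110), seed = 60)
  ref <- campaign_reference_stats(cmp, "dv50",
                                  exclude = batch_ids(cmp)[1L])
  keep <- batch_ids(cmp)[-1L]
  vals <- unlist(lapply(cmp$batches[keep], function(b) b$sizes[, 3L]))
  expect_equal(ref$sd, sd(vals))
  expect_equal(ref$range, max(vals) - min(vals))
  ends <- vapply(cmp$batches[keep],
                 function(b) b$sizes[nrow(b$sizes), 3L], numeric(1))
  expect_equal(ref$lab_error, sd(ends))
})

test_that("run_comparison keeps test rows out of fitting and reports 273
           merged predictors", {
  cmp <- tiny_campaign(4, rows = c(100, 130), seed = 61)
  rep1 <- run_comparison(cmp, "ma1", c("nir", "pars", "merged"), "dv50",
                         max_lv = 5, keep_models = TRUE)
  expect_identical(nrow(rep1$results), 12L)
  expect_length(rep1$models[[1L]]$B, 273L)
  expect_true(all(rep1$results$rmsep > 0))
  expect_true(all(rep1$results$n_lv <= 5L))
  # ratio identities hold for every reported bundle
  ref <- rep1$reference
  expect_equal(rep1$results$rpd * rep1$results$rmsep,
               rep(ref$sd, 12L), tolerance = 1e-10)
  # across-batch approach: each batch predicted exactly once
  rep2 <- run_comparison(cmp, "ma2b", "nir", "dv50", max_lv = 4)
  expect_identical(sort(rep2$results$batch_id), sort(batch_ids(cmp)))
  expect_error(run_comparison(cmp, "ma1", "nir", targets = "dv55"),
               "dv55")
})

test_that("the merged predictor set can include the smoothed spray rate", {
  cmp <- tiny_campaign(2, rows = c(100, 120), seed = 62)
  rep18 <- run_comparison(cmp, "ma1", "merged", "dv50", max_lv = 4,
                          include_spray_rate = TRUE, keep_models = TRUE)
  expect_length(rep18$models[[1L]]$B, 274L)
  expect_true("spray_rate" %in% names(rep18$models[[1L]]$B))
})

test_that("paired comparison handles ties, dominance and degeneracy", {
  expect_equal(paired_rmsep_test(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(63)
  a <- runif(10, 1, 2)
  b <- a + runif(10, 3, 4)
  expect_lt(paired_rmsep_test(a, b), 1e-4)
  # textbook oracle
  d <- a - b
  tval <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(paired_rmsep_test(a, b),
               pt(tval, length(d) - 1))
  expect_error(paired_rmsep_test(a, a + 1), "zero variance")
  expect_error(paired_rmsep_test(1, 2), "length >= 2")
})

test_that("coefficient importance averages |B| and ranks parameters", {
  cmp <- tiny_campaign(3, rows = c(90, 120), seed = 64)
  rep1 <- run_comparison(cmp, "ma1", "merged", "dv50", max_lv = 4,
                         keep_models = TRUE)
  ci <- coefficient_importance(rep1$models)
  expect_identical(nrow(ci$parameters), 17L)
  expect_false(is.unsorted(rev(ci$parameters$abs_coef)))
  expect_equal(ci$margin, ci$nir_mean + 2 * ci$nir_sd)
  # single model reduces to its own absolute coefficients
  ci1 <- coefficient_importance(rep1$models[1L])
  b1 <- abs(rep1$models[[1L]]$coef_scaled)
  expect_equal(sort(ci1$parameters$abs_coef, decreasing = TRUE),
               sort(unname(b1[257:273]), decreasing = TRUE))
  # ranking stable under model order permutation
  ci_rev <- coefficient_importance(rev(rep1$models))
  expect_identical(ci$parameters$parameter, ci_rev$parameters$parameter)
})

test_that("the moisture hold-out assigns every fifth pooled row to test", {
  lodded <- lapply(1:10, function(i) {
    manual_batch(30, batch_id = paste0("b", i),
                 lod = data.frame(row = seq(2, 30, by = 2),
                                  value = runif(15, 1, 8)),
                 seed = i)
  })
  cmp <- campaign(lodded)
  lh <- lod_holdout(cmp)
  expect_length(lh$train, 120L)
  expect_length(lh$test, 30L)
  expect_identical(lh$test, seq(5L, 150L, by = 5L))
  small <- campaign(lodded[1L])
  lh2 <- lod_holdout(small)
  expect_length(lh2$train, 12L)
  expect_length(lh2$test, 3L)
})
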