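test_that("full-rank PLS equals least squares and is permutation-stable", {
  set.seed(10)
  for (i in 1:5) {
    X <- matrix(rnorm(200), 20, 10)
    y <- rnorm(20)
    m <- fit_pls(X, y, n_lv = 10)
    ols <- lm(y ~ X)
    expect_lt(max(abs(predict(m, X) - fitted(ols))), 1e-10)
    perm <- sample(20)
    m2 <- fit_pls(X[perm, ], y[perm], n_lv = 10)
    expect_equal(m2$B, m$B, tolerance = 1e-9)
  }
})

test_that("an exactly linear response is recovered with one component", {
  # orthogonal predictor columns, so the first weight vector points
  # exactly along the informative column
  X <- unclass(stats::poly(1:30, 10))
  y <- 2.5 * X[, 3L]
  m <- fit_pls(X, y, n_lv = 1)
  expect_lt(m$rmsec, 1e-8)
})

test_that("predictions agree with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  colnames(X) <- paste0("x", 1:10)
  y <- rnorm(20)
  m <- fit_pls(X, y, n_lv = 3)
  ref <- mixOmics::pls(data.frame(X), y, ncomp = 3, mode = "regression",
                       scale = TRUE)
  ref_pred <- predict(ref, data.frame(X))$predict[, 1L, 3L]
  expect_lt(max(abs(predict(m, X) - ref_pred)), 1e-8)
})

test_that("predict applies the stored model without refitting", {
  set.seed(13)
  X <- matrix(rnorm(150), 15, 10)
  y <- rnorm(15)
  m <- fit_pls(X, y, 2)
  expect_equal(predict(m, X), as.numeric(X %*% m$B + m$intercept))
  expect_length(predict(m, X[1L, , drop = FALSE]), 1L)
  expect_error(predict(m, X[, 1:5]), "columns")
  expect_error(fit_pls(X, y, 15), "n_lv")
  expect_error(fit_pls(X, y[-1L], 2), "same number of rows")
})

test_that("cv_plan schemes partition rows as specified", {
  p <- cv_plan("loo", 7)
  expect_identical(p$fold, 1:7)
  p <- cv_plan("sequential_k", 10, 3)
  expect_identical(p$fold, ((0:9) %% 3L) + 1L)
  p <- cv_plan("block_k", 100, 10)
  expect_identical(as.integer(table(p$fold)), rep(10L, 10))
  expect_false(is.unsorted(p$fold))
  p <- cv_plan("block_k", 101, 10)
  expect_identical(as.integer(table(p$fold)), c(11L, rep(10L, 9)))
  expect_error(cv_plan("sequential_k", 5, 1), "k must")
  expect_error(cv_plan("block_k", 5, 6), "k must")
})

test_that("cross-validation matches a brute-force fold loop", {
  set.seed(14)
  X <- matrix(rnorm(240), 24, 10)
  y <- rnorm(24)
  plan <- cv_plan("sequential_k", 24, 4)
  cv <- cross_validate(X, y, plan, 3)
  manual <- numeric(24)
  for (k in 1:4) {
    te <- which(plan$fold == k)
    mk <- fit_pls(X[-te, ], y[-te], 3)
    manual[te] <- predict(mk, X[te, , drop = FALSE])
  }
  expect_lt(abs(cv$rmsecv - sqrt(mean((manual - y)^2))), 1e-10)
  expect_equal(cv$predictions, manual, tolerance = 1e-10)
  # loo runs one submodel per row
  loo <- cross_validate(X, y, cv_plan("loo", 24), 2)
  expect_length(loo$residuals, 24L)
  expect_error(cross_validate(X, y, cv_plan("loo", 10), 2), "covers")
  tiny <- cv_plan("sequential_k", 8, 2)
  expect_error(cross_validate(matrix(rnorm(64), 8, 8), rnorm(8), tiny, 6),
               "components|training rows")
})

test_that("a low-noise calibration shows no CV optimism", {
  set.seed(15)
  X <- matrix(rnorm(5000), 500, 10)
  y <- as.numeric(X %*% runif(10, 0.5, 1)) + rnorm(500, 0, 0.01)
  plan <- cv_plan("sequential_k", 500, 10)
  cv <- cross_validate(X, y, plan, 5)
  m <- fit_pls(X, y, 5)
  expect_equal(cv$rmsecv / m$rmsec, 1, tolerance = 0.05)
})

test_that("component selection takes the parsimonious RMSECV minimum", {
  set.seed(16)
  X <- matrix(rnorm(400), 40, 10)
  y <- as.numeric(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(40, 0, 0.2)
  plan <- cv_plan("sequential_k", 40, 5)
  got <- select_n_lv(X, y, plan, max_lv = 8)
  path <- cross_validate(X, y, plan, 8)$rmsecv_path
  expect_identical(got, which(path <= min(path) + 1e-12)[1L])
})

test_that("metric bundle reproduces the standardized ratio definitions", {
  ref <- make_reference_stats(c(1, 3, 5, 9), lab_error = 0.5)
  expect_equal(ref$range, 8)
  obs <- c(2, 4, 6)
  pred <- c(2.5, 3.5, 6.5)
  mb <- prediction_metrics(obs, pred, ref)
  expect_equal(mb$rmsep, 0.5)
  expect_equal(mb$rpd * mb$rmsep, ref$sd)
  expect_equal(mb$rer, ref$range / mb$rmsep)
  expect_equal(mb$prl, mb$rmsep / ref$lab_error)
  expect_equal(mb$rpiq, ref$iqr / mb$rmsep)
  perfect <- prediction_metrics(obs, obs)
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$r2_test, 1)
  expect_error(prediction_metrics(obs, obs, ref), "zero")
})

test_that("ratio metrics reproduce the published reference cells", {
  tb <- study_tables()
  ref <- tb$dv50_reference[tb$dv50_reference$group == "non_outliers", ]
  r <- ratio_metrics_row(c(68.3, 38.8), ref)
  expect_equal(round(r$rpd[1L], 2), 2.03)
  expect_equal(round(r$rer[2L], 1), 19.9)
  expect_equal(round(r$prl[1L], 2), 0.97)
  expect_equal(round(r$rpiq[1L], 2), 2.81)
})
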