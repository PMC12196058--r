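test_that("PCA model reconstructs the data and fixes component signs", {
  set.seed(20)
  X <- matrix(rnorm(30 * 8), 30, 8) %*% matrix(rnorm(64), 8, 8)
  m <- fit_pca(X, scale_all = TRUE)
  expect_equal(sum(m$explained), 1, tolerance = 1e-10)
  expect_equal(sum(m$kaiser_scores), ncol(X), tolerance = 1e-8)
  # largest-magnitude loading entry is positive in every component
  for (j in seq_len(ncol(m$loadings))) {
    v <- m$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # scores %*% t(loadings) reconstructs the scaled, centered data
  Xs <- scale(X)
  expect_equal(m$scores %*% t(m$loadings), Xs, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(X[1L, , drop = FALSE]), "2 rows")
  Xz <- X; Xz[, 2L] <- 1
  expect_error(fit_pca(Xz), "zero-variance")
})

test_that("Kaiser scores behave on isotropic and structured data", {
  set.seed(21)
  iso <- matrix(rnorm(4000 * 20), 4000, 20)
  m <- fit_pca(iso)
  expect_true(all(abs(m$kaiser_scores - 1) < 0.15))
  # score = n_variables x explained fraction
  expect_equal(m$kaiser_scores, 20 * m$explained)
})

test_that("the combined component rule trims the strict Kaiser count", {
  # Kaiser-score sequence with a clear elbow after five components; the
  # strict rule keeps everything above 1, the combined rule stops at the
  # elbow
  ks <- c(205, 25.4, 10, 4.77, 3.44, 1.1, 1.03, 0.4, 0.15, 0.05)
  expect_identical(choose_n_pc(ks, use_scree = FALSE), 7L)
  expect_identical(choose_n_pc(ks), 5L)
  expect_identical(choose_n_pc(c(0.9, 0.05, 0.01)), 1L)   # all below 1
  expect_identical(choose_n_pc(c(200, 0.5, 0.3, 0.1)), 1L) # one dominant
})

test_that("PC-space Mahalanobis distances match the quadratic-form oracle", {
  set.seed(22)
  X <- matrix(rnorm(60 * 10, 5, 2), 60, 10)
  m <- fit_pca(X)
  d <- mahalanobis_pc(m, 4)
  S <- m$scores[, 1:4]
  oracle <- sqrt(stats::mahalanobis(S, colMeans(S), stats::cov(S)))
  expect_equal(d$distance, oracle, tolerance = 1e-10)
  expect_identical(d$flagged, oracle > 3)
  # the population mean row projects to the score centroid: distance 0
  ctr <- mahalanobis_pc(m, 4, rows = matrix(colMeans(X), 1L))
  expect_lt(ctr$distance, 1e-8)
  expect_error(mahalanobis_pc(m, 11), "exceeds")
})

test_that("SIMCA p-values follow the one-sample t construction", {
  set.seed(23)
  d2 <- c(rnorm(30, 10, 2), 10, 25, 6)
  ref <- 1:30
  p <- simca_p(d2, 31:33, ref)
  # candidate exactly at the reference mean -> p = 0.5
  d2[31L] <- mean(d2[ref])
  p <- simca_p(d2, 31:33, ref)
  expect_equal(p[1L], 0.5)
  # monotone decreasing in the squared distance
  expect_lt(p[2L], p[1L])
  expect_gt(p[3L], p[1L])
  # textbook oracle
  n <- length(ref)
  tval <- (d2[32L] - mean(d2[ref])) / (sd(d2[ref]) * sqrt(1 + 1 / n))
  expect_equal(p[2L], pt(tval, n - 1, lower.tail = FALSE))
  expect_error(simca_p(d2, 31L, 1:2), "at least 3")
  expect_error(simca_p(rep(1, 10), 1L, 2:5), "zero-variance")
})

test_that("BBE-PLS never eliminates at alpha zero and reports every cycle", {
  cmp <- tiny_campaign(4, rows = c(80, 110), seed = 30)
  r <- bbe_pls(cmp, alpha = 0)
  expect_length(r$eliminated, 0L)
  expect_identical(r$surviving, batch_ids(cmp))
  expect_equal(nrow(r$cycles), 1L)
  expect_false(r$cycles$eliminated)
  # the candidate is the RMSECV argmin, so after <= before is structural
  expect_lte(r$cycles$rmsecv_after, r$cycles$rmsecv_before)
  expect_error(bbe_pls(tiny_campaign(2, rows = c(60, 70))), "3 batches")
})

test_that("the eliminated set is invariant to batch ordering", {
  cfg <- sim_config(n_batches = 8, rows_per_batch = c(100, 140), seed = 31,
                    outlier_ids = c("0930", "1129"))
  cmp <- simulate_campaign(cfg)$campaign
  r1 <- bbe_pls(cmp)
  perm <- rev(batch_ids(cmp))
  cmp_perm <- campaign(cmp$batches[perm], grid = cmp$grid,
                       paramset = cmp$paramset)
  r2 <- bbe_pls(cmp_perm)
  expect_setequal(r1$eliminated, r2$eliminated)
  expect_true(all(c("0930", "1129") %in% r1$eliminated))
})

test_that("the full screen bundles distances, SIMCA and BBE coherently", {
  cfg <- sim_config(n_batches = 8, rows_per_batch = c(120, 160), seed = 21,
                    outlier_ids = "1011")
  cmp <- simulate_campaign(cfg)$campaign
  scr <- outlier_screen(cmp)
  expect_true(all(scr$simca$p_value >= 0 & scr$simca$p_value <= 1))
  expect_identical(nrow(scr$mahalanobis),
                   as.integer(sum(vapply(cmp$batches,
                                         function(b) nrow(b$lod),
                                         numeric(1)))))
  expect_identical(scr$flagged_batches, scr$bbe$eliminated)
  # the corrupted batch carries the lowest SIMCA membership p-value
  p <- scr$simca
  expect_identical(p$batch_id[which.min(p$p_value)], "1011")
})
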