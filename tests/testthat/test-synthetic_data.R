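test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_batches = 2, rows_per_batch = c(60, 80), seed = 9)
  a <- simulate_batch(cfg, "b", seed = 123)
  b <- simulate_batch(cfg, "b", seed = 123)
  expect_identical(a$batch$spectra, b$batch$spectra)
  expect_identical(a$batch$params, b$batch$params)
  expect_identical(a$truth$dv50, b$truth$dv50)
  c1 <- simulate_campaign(cfg)$campaign
  c2 <- simulate_campaign(cfg)$campaign
  expect_identical(c1$batches[[2L]]$sizes, c2$batches[[2L]]$sizes)
})

test_that("generated batches satisfy the structural invariants", {
  for (s in 1:5) {
    cfg <- sim_config(n_batches = 1, rows_per_batch = c(80, 120), seed = s)
    b <- simulate_batch(cfg, "t", seed = s)$batch
    expect_silent(validate_batch_record(b))
    expect_false(is.unsorted(b$times))
    # spray phase first, then drying; spray rate zero exactly in drying
    expect_identical(b$phase, sort(b$phase, decreasing = TRUE))
    sr <- b$params[, "spray_rate"]
    expect_true(all(sr[b$phase == "spray"] > 0))
    expect_true(all(sr[b$phase == "drying"] == 0))
    # Dv ordering row-wise
    expect_false(any(apply(b$sizes, 1L, is.unsorted)))
    expect_true(all(b$lod$value >= 0 & b$lod$value <= 100))
    tr <- simulate_batch(cfg, "t", seed = s)$truth
    expect_true(any(tr$informative[1:256]))
    expect_true(any(tr$informative[-(1:256)]))
  }
})

test_that("zero growth gain freezes the size trajectory during spray", {
  cfg <- sim_config(n_batches = 1, rows_per_batch = c(100, 100), seed = 2,
                    growth_gain = 0)
  r <- simulate_batch(cfg, "t", seed = 5)
  spray_dv <- r$truth$dv50[r$batch$phase == "spray"]
  expect_equal(stats::sd(spray_dv), 0)
})

test_that("noiseless spectra are an exact function of the two latents", {
  cfg <- sim_config(n_batches = 1, rows_per_batch = c(90, 90), seed = 3,
                    noise_sd = 0, scatter_sd = 0)
  r <- simulate_batch(cfg, "t", seed = 7)
  # every channel is linear in (dv50, moisture) once noise and scatter are
  # off, so a per-channel regression on the latents leaves no residual
  lat <- cbind(1, r$truth$dv50, r$truth$moisture)
  resid <- r$batch$spectra - lat %*% qr.solve(lat, r$batch$spectra)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("campaign-level config errors are caught", {
  expect_error(sim_config(n_batches = 0), "n_batches")
  expect_error(sim_config(spray_fraction = 1.2), "spray_fraction")
  expect_error(sim_config(ar1_rho = 1), "ar1_rho")
  cfg <- sim_config(n_batches = 2, rows_per_batch = c(60, 60),
                    batch_ids = c("a", "a"))
  expect_error(simulate_campaign(cfg), "duplicate")
  cfg2 <- sim_config(n_batches = 2, rows_per_batch = c(60, 60),
                     outlier_ids = "zz")
  expect_error(simulate_campaign(cfg2), "outlier_ids")
})

test_that("total rows fall within the configured range", {
  cfg <- sim_config(n_batches = 4, rows_per_batch = c(70, 90), seed = 6)
  cmp <- simulate_campaign(cfg)$campaign
  n <- vapply(cmp$batches, function(b) length(b$times), numeric(1))
  expect_true(all(n >= 70 & n <= 90))
})

test_that("outlier injection shifts parameters beyond the clean cloud", {
  cfg <- sim_config(n_batches = 8, rows_per_batch = c(80, 110), seed = 13,
                    outlier_ids = c("1005", "1128"))
  cmp <- simulate_campaign(cfg)$campaign
  clean_ids <- setdiff(batch_ids(cmp), c("1005", "1128"))
  clean_atom <- unlist(lapply(cmp$batches[clean_ids],
                              function(b) b$params[, "atomizing_pressure"]))
  # '1005' is the high extreme: its mean atomizing pressure exceeds every
  # clean-batch row value
  expect_gt(mean(cmp$batches[["1005"]]$params[, "atomizing_pressure"]),
            max(clean_atom))
  # the low extreme is pushed well below the clean average (how far below
  # depends on where its own setpoint started)
  expect_lt(mean(cmp$batches[["1128"]]$params[, "atomizing_pressure"]),
            mean(clean_atom) - 0.5 * stats::sd(clean_atom))
})

test_that("magnitude zero leaves the batch unchanged; bad mode errors", {
  b <- tiny_campaign(1)$batches[[1L]]
  out <- inject_outlier_batch(b, "high_extreme", magnitude = 0,
                              param_sds = c(airflow_rate = 1))
  expect_identical(out$spectra, b$spectra)
  expect_identical(out$params, b$params)
  expect_error(inject_outlier_batch(b, "sideways", 1, c(airflow_rate = 1)),
               "arg")
  expect_error(inject_outlier_batch(b, "high_extreme", -1,
                                    c(airflow_rate = 1)), "magnitude")
})

test_that("an injected outlier batch is flagged by the full screen", {
  cfg <- sim_config(n_batches = 8, rows_per_batch = c(120, 160), seed = 21,
                    outlier_ids = "1011")
  cmp <- simulate_campaign(cfg)$campaign
  scr <- outlier_screen(cmp)
  expect_true("1011" %in% scr$flagged_batches)
})
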