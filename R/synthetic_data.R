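# Synthetic granulation campaigns with the statistical structure the
# downstream chemometrics assumes: a spray phase growing granules at a rate
# coupled to spray rate, airflow and atomization, a terminal drying phase,
# size-dependent spectral baselines, moisture-dependent water bands, AR(1)
# process-parameter noise, and injectable extreme-parameter outlier batches.

# Setpoint ranges per parameter (low, high, within-batch noise SD). The
# airflow range matches the unit's 18.7-36.0 m3/h operating window; the
# others are plausible ranges for a lab-scale fluid-bed unit.
PARAM_RANGES <- list(
  airflow_rate            = c(18.7, 36.0, 0.60),
  atomizing_pressure      = c(0.8, 2.5, 0.05),
  pht_out_temp            = c(24, 38, 0.40),
  inlet_air_temp          = c(40, 70, 0.80),
  plenum_pressure         = c(1000, 1040, 1.50),
  exhaust_pressure        = c(990, 1020, 1.50),
  pht_in_abs_hum          = c(4, 11, 0.25),
  pht_in_rel_hum          = c(20, 60, 1.20),
  pht_out_rel_hum         = c(25, 75, 1.50),
  pht_out_abs_hum         = c(6, 16, 0.35),
  exhaust_temp            = c(26, 42, 0.50),
  pht_out_pressure        = c(995, 1015, 1.20),
  product_temp            = c(29, 33, 0.40),
  pht_in_pressure         = c(1005, 1030, 1.20),
  prod_filt_diff_pressure = c(5, 8, 0.25),
  pht_in_temp             = c(20, 32, 0.40)
)

# Parameters shifted when a batch is corrupted into an extreme-settings
# outlier (the batch then sits at the high or low end of all of these at
# once, far outside the clean operating cloud).
OUTLIER_SHIFT_PARAMS <- c(
  "airflow_rate", "atomizing_pressure", "inlet_air_temp", "exhaust_temp",
  "product_temp", "pht_in_pressure", "pht_out_pressure"
)

# Batch ids used for a default 14-batch campaign.
DEFAULT_BATCH_IDS <- c(
  "0802", "0920", "0930", "1005", "1011", "1020", "1128", "1129", "1203",
  "1212", "1213", "1214", "1229", "1230"
)

#' Configuration for the synthetic campaign generator
#'
#' Defaults emulate a 14-batch granulation study: 2000-3000 acquisition rows
#' per batch, ~70% of rows in the spray phase, about 12 sparse LOD moisture
#' measurements per batch, and two batches corrupted into extreme-parameter
#' outliers.
#'
#' @param n_batches number of batches.
#' @param rows_per_batch length-2 range of rows per batch (drawn uniformly).
#' @param seed integer root seed; per-batch seeds are derived from it.
#' @param spray_fraction fraction of rows in the spray phase.
#' @param growth_gain um of Dv50 growth per (g/min) of spray rate per step.
#' @param airflow_effect,atomization_effect signed sensitivities of the
#'   growth rate to standardized airflow and atomizing pressure. Setting
#'   both to 0 decouples the parameter block from the granule state
#'   entirely: growth no longer depends on parameters, the state-responsive
#'   parameter terms (bed pressure drop tracking granule size, product
#'   temperature tracking bed moisture) are switched off, and so is the
#'   parameter-driven spectral nuisance.
#' @param baseline_gain absorbance baseline offset per um of Dv50.
#' @param slope_gain wavelength-slope of the size-dependent baseline, as a
#'   fraction of `baseline_gain` across the grid.
#' @param water_band_centers water absorption band centers, nm.
#' @param band_width_nm Gaussian band sigma, nm.
#' @param moisture_gain absorbance per % LOD at a water band peak.
#' @param noise_sd additive spectral noise SD (absorbance).
#' @param scatter_sd SD of the per-row multiplicative scatter factor
#'   (0 disables scatter).
#' @param ar1_rho AR(1) autocorrelation of process-parameter noise.
#' @param response_sd SD of the per-batch lognormal perturbation of the
#'   spectral size-response gain (probe optics / packing differences between
#'   batches); 0 makes every batch share one spectral response.
#' @param nuisance_gain amplitude of the batch-level spectral nuisance: a
#'   curvature-shaped baseline component whose per-batch coefficient is
#'   driven by the airflow and atomization setpoints (through the same
#'   `airflow_effect`/`atomization_effect` switches), emulating
#'   condition-dependent probe/window optics that confound purely spectral
#'   size prediction across batches.
#' @param outlier_ids batch ids to corrupt (high extreme first, then low,
#'   alternating).
#' @param outlier_magnitude parameter shift in campaign-SD units.
#' @param lod_points_per_batch expected LOD measurements per batch.
#' @param batch_ids optional explicit batch id labels.
#' @param include_spray_rate keep spray rate as an 18th parameter column?
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_batches = 14L,
                       rows_per_batch = c(2000L, 3000L),
                       seed = 1L,
                       spray_fraction = 0.7,
                       growth_gain = 0.008,
                       airflow_effect = 0.5,
                       atomization_effect = -0.3,
                       baseline_gain = 0.002,
                       slope_gain = 0.6,
                       water_band_centers = c(1450, 1934),
                       band_width_nm = 45,
                       moisture_gain = 0.03,
                       noise_sd = 0.008,
                       scatter_sd = 0.08,
                       ar1_rho = 0.97,
                       response_sd = 0.3,
                       nuisance_gain = 0.1,
                       outlier_ids = character(0L),
                       outlier_magnitude = 3,
                       lod_points_per_batch = 12L,
                       batch_ids = NULL,
                       include_spray_rate = TRUE) {
  cfg <- list(
    n_batches = as.integer(n_batches),
    rows_per_batch = as.integer(rows_per_batch),
    seed = as.integer(seed),
    spray_fraction = spray_fraction,
    growth_gain = growth_gain,
    airflow_effect = airflow_effect,
    atomization_effect = atomization_effect,
    baseline_gain = baseline_gain,
    slope_gain = slope_gain,
    water_band_centers = water_band_centers,
    band_width_nm = band_width_nm,
    moisture_gain = moisture_gain,
    noise_sd = noise_sd,
    scatter_sd = scatter_sd,
    ar1_rho = ar1_rho,
    response_sd = response_sd,
    nuisance_gain = nuisance_gain,
    outlier_ids = as.character(outlier_ids),
    outlier_magnitude = outlier_magnitude,
    lod_points_per_batch = as.integer(lod_points_per_batch),
    batch_ids = batch_ids,
    include_spray_rate = isTRUE(include_spray_rate)
  )
  if (cfg$n_batches < 1L) stop("n_batches must be >= 1", call. = FALSE)
  if (length(cfg$rows_per_batch) == 1L)
    cfg$rows_per_batch <- rep(cfg$rows_per_batch, 2L)
  if (any(cfg$rows_per_batch < 10L))
    stop("rows_per_batch must be >= 10", call. = FALSE)
  if (cfg$spray_fraction <= 0 || cfg$spray_fraction >= 1)
    stop("spray_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (abs(cfg$ar1_rho) >= 1) stop("|ar1_rho| must be < 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

ar1_noise <- function(n, rho, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                           method = "recursive",
                           init = stats::rnorm(1L, 0, sd)))
}

gaussian_band <- function(grid, center, sigma) {
  exp(-0.5 * ((as.numeric(grid) - center) / sigma)^2)
}

# Dv percentile span factors relative to Dv50, preserving ordering.
DV_SPAN <- c(dv10 = 0.45, dv25 = 0.7, dv50 = 1, dv75 = 1.4, dv90 = 1.9)

#' Simulate one granulation batch
#'
#' Generates a spray phase followed by a drying phase. During spray the
#' latent Dv50 grows at `growth_gain * spray_rate * g(airflow, atomization)`
#' with `g = exp(airflow_effect * z_air + atomization_effect * z_atom)`
#' (z = standardized deviation from the mid-range setpoint), and latent
#' moisture rises towards a wet equilibrium; during drying spray rate is
#' exactly zero, moisture decays exponentially and sizes shrink mildly.
#' Spectra are built as a size-dependent baseline (offset + wavelength
#' slope), fixed formulation bands, moisture-scaled water bands at 1450 and
#' 1934 nm, per-row multiplicative scatter and additive Gaussian noise.
#'
#' @param cfg a [sim_config()].
#' @param batch_id label for the batch.
#' @param seed integer seed for this batch.
#' @return list with elements `batch` ([batch_record()]) and `truth`
#'   (latent moisture/size trajectories and the informative-variable mask).
#' @export
simulate_batch <- function(cfg, batch_id, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  grid <- spectral_grid()
  n <- if (cfg$rows_per_batch[1L] == cfg$rows_per_batch[2L])
    cfg$rows_per_batch[1L]
  else sample(seq(cfg$rows_per_batch[1L], cfg$rows_per_batch[2L]), 1L)
  n_spray <- max(1L, min(n - 1L, round(cfg$spray_fraction * n)))
  phase <- rep(c("spray", "drying"), c(n_spray, n - n_spray))
  times <- seq(0, by = 2, length.out = n)

  # process-parameter trajectories: batch setpoint + AR(1) noise
  pnames <- process_parameters()
  params <- matrix(NA_real_, n, length(pnames),
                   dimnames = list(NULL, pnames))
  setpt <- numeric(length(pnames))
  names(setpt) <- pnames
  for (p in names(PARAM_RANGES)) {
    r <- PARAM_RANGES[[p]]
    setpt[p] <- stats::runif(1L, r[1L] + 0.1 * (r[2L] - r[1L]),
                             r[2L] - 0.1 * (r[2L] - r[1L]))
    params[, p] <- setpt[p] + ar1_noise(n, cfg$ar1_rho, r[3L])
  }
  params[, "runtime"] <- times

  # spray rate: positive during spray, exactly zero during drying
  spray_setpt <- stats::runif(1L, 18, 22)
  spray_rate <- numeric(n)
  spray_rate[seq_len(n_spray)] <-
    pmax(0.5, spray_setpt + ar1_noise(n_spray, cfg$ar1_rho, 0.8))

  # latent moisture (% LOD): rises during spray, decays during drying
  z_air <- (params[, "airflow_rate"] - mean(PARAM_RANGES$airflow_rate[1:2])) /
    diff(PARAM_RANGES$airflow_rate[1:2]) * 2
  z_atom <- (params[, "atomizing_pressure"] -
               mean(PARAM_RANGES$atomizing_pressure[1:2])) /
    diff(PARAM_RANGES$atomizing_pressure[1:2]) * 2
  moisture <- numeric(n)
  m <- stats::runif(1L, 1.5, 3)
  # rates scale with phase length so every batch traverses a realistic
  # LOD excursion (wetting to ~8-10 %, drying back down) regardless of
  # how many rows it holds
  wet_gain <- 0.4 / n_spray
  dry_rate <- 5 / max(1L, n - n_spray)
  for (i in seq_len(n)) {
    if (phase[i] == "spray") {
      m <- m + wet_gain * spray_rate[i] - 0.3 / n_spray * m
    } else {
      m <- m * (1 - dry_rate)
    }
    moisture[i] <- m
  }

  # latent Dv50 (um): parameter-coupled growth, mild decay while drying
  g <- exp(cfg$airflow_effect * z_air + cfg$atomization_effect * z_atom)
  dv50 <- numeric(n)
  s <- stats::runif(1L, 120, 170)
  for (i in seq_len(n)) {
    if (phase[i] == "spray") {
      s <- s + cfg$growth_gain * spray_rate[i] * g[i]
    } else {
      s <- s * (1 - 2e-5)
    }
    dv50[i] <- s
  }
  # state-responsive parameters (only when parameter coupling is on):
  # coarser granules lower the product/filter pressure drop; a wet bed
  # depresses the product temperature
  coupled <- cfg$airflow_effect != 0 || cfg$atomization_effect != 0
  if (coupled) {
    params[, "prod_filt_diff_pressure"] <-
      params[, "prod_filt_diff_pressure"] - 0.04 * (dv50 - 150)
    params[, "product_temp"] <- params[, "product_temp"] -
      0.8 * (moisture - 2)
  }

  dv50_meas <- dv50 * exp(stats::rnorm(n, 0, 0.01))
  sizes <- outer(dv50_meas, DV_SPAN)
  colnames(sizes) <- SIZE_COLUMNS

  # spectra: size baseline + formulation bands + moisture water bands
  wl <- as.numeric(grid)
  wl01 <- (wl - min(wl)) / diff(range(wl))
  base_shape <- 1 + cfg$slope_gain * (wl01 - 0.5)
  form_bands <- 0.15 * gaussian_band(grid, 1200, 60) +
    0.25 * gaussian_band(grid, 1700, 55) +
    0.20 * gaussian_band(grid, 2050, 70)
  water <- rowSums(vapply(cfg$water_band_centers, gaussian_band,
                          numeric(length(wl)), grid = grid,
                          sigma = cfg$band_width_nm))
  chem <- outer(rep(1, n), form_bands) +
    cfg$moisture_gain * outer(moisture, water)
  scatter <- if (cfg$scatter_sd > 0)
    exp(stats::rnorm(n, 0, cfg$scatter_sd)) else rep(1, n)
  # batch-level optical nuisance: curvature baseline whose coefficient is
  # set by the airflow/atomization setpoints (zero when both effects are 0)
  z_air_set <- (setpt["airflow_rate"] - mean(PARAM_RANGES$airflow_rate[1:2])) /
    diff(PARAM_RANGES$airflow_rate[1:2]) * 2
  z_atom_set <- (setpt["atomizing_pressure"] -
                   mean(PARAM_RANGES$atomizing_pressure[1:2])) /
    diff(PARAM_RANGES$atomizing_pressure[1:2]) * 2
  nuis_coef <- cfg$nuisance_gain *
    (cfg$airflow_effect * z_air_set + cfg$atomization_effect * z_atom_set)
  nuis_shape <- 4 * (wl01 - 0.5)^2
  gain_b <- cfg$baseline_gain * exp(stats::rnorm(1L, 0, cfg$response_sd))
  spectra <- outer(gain_b * dv50, base_shape) + scatter * chem +
    nuis_coef * outer(rep(1, n), nuis_shape)
  if (cfg$noise_sd > 0)
    spectra <- spectra + matrix(stats::rnorm(n * length(wl), 0, cfg$noise_sd),
                                n, length(wl))
  colnames(spectra) <- wavelength_colnames(grid)

  # sparse LOD measurements: latent moisture + small gravimetric error
  n_lod <- min(n, max(2L, stats::rpois(1L, cfg$lod_points_per_batch)))
  lod_rows <- sort(sample.int(n, n_lod))
  lod_vals <- pmin(100, pmax(0, moisture[lod_rows] +
                               stats::rnorm(n_lod, 0, 0.05)))

  if (cfg$include_spray_rate) params <- cbind(params, spray_rate = spray_rate)
  params <- params[, process_parameters(cfg$include_spray_rate), drop = FALSE]

  b <- batch_record(batch_id, times, spectra, params, sizes,
                    lod = data.frame(row = lod_rows, value = lod_vals),
                    phase = phase)

  # informative-variable mask over 256 spectral + parameter predictors
  spec_info <- base_shape > 0 |
    form_bands > 0.02 | water > 0.02  # baseline affects every channel
  param_info <- process_parameters(cfg$include_spray_rate) %in%
    c("airflow_rate", "atomizing_pressure", "runtime",
      if (cfg$include_spray_rate) "spray_rate")
  truth <- list(moisture = moisture, dv50 = dv50,
                informative = c(spec_info, param_info))
  list(batch = b, truth = truth)
}

#' Simulate a whole campaign
#'
#' Batches receive seeds derived from `cfg$seed`; ids listed in
#' `cfg$outlier_ids` are corrupted with [inject_outlier_batch()]
#' (alternating high/low extremes) after the clean campaign is generated, so
#' the shift magnitude is expressed in clean-campaign SD units.
#'
#' @param cfg a [sim_config()].
#' @return list with `campaign` ([campaign()]) and `truth` (per-batch list).
#' @export
simulate_campaign <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- cfg$batch_ids
  if (is.null(ids)) {
    ids <- if (cfg$n_batches <= length(DEFAULT_BATCH_IDS))
      DEFAULT_BATCH_IDS[seq_len(cfg$n_batches)]
    else sprintf("b%03d", seq_len(cfg$n_batches))
  }
  if (anyDuplicated(ids))
    stop("duplicate batch ids in configuration", call. = FALSE)
  if (length(ids) != cfg$n_batches)
    stop("batch_ids length must equal n_batches", call. = FALSE)
  unknown <- setdiff(cfg$outlier_ids, ids)
  if (length(unknown))
    stop("outlier_ids not in campaign: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sims <- vector("list", cfg$n_batches)
  for (i in seq_len(cfg$n_batches)) {
    sims[[i]] <- simulate_batch(cfg, ids[i],
                                seed = (cfg$seed * 1000L + i) %% 2147483647L)
  }
  batches <- lapply(sims, `[[`, "batch")
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- ids

  if (length(cfg$outlier_ids)) {
    clean <- setdiff(ids, cfg$outlier_ids)
    pool <- do.call(rbind, lapply(batches[match(clean, ids)],
                                  function(b) b$params))
    param_sds <- apply(pool, 2L, stats::sd)
    modes <- rep(c("high_extreme", "low_extreme"),
                 length.out = length(cfg$outlier_ids))
    for (j in seq_along(cfg$outlier_ids)) {
      i <- match(cfg$outlier_ids[j], ids)
      batches[[i]] <- inject_outlier_batch(
        batches[[i]], mode = modes[j], magnitude = cfg$outlier_magnitude,
        param_sds = param_sds,
        seed = (cfg$seed * 1000L + 500L + j) %% 2147483647L
      )
    }
  }
  list(
    campaign = campaign(batches,
                        paramset = process_parameters(cfg$include_spray_rate)),
    truth = truth
  )
}

#' Corrupt a batch into an extreme-parameter outlier
#'
#' Shifts a fixed subset of process parameters by `magnitude` campaign SDs
#' (sign per `mode`) and distorts the spectra: an added baseline offset and
#' wavelength slope plus a rescaled moisture-band response, so the batch
#' separates from the clean cloud in PC-score space and degrades a pooled
#' spectra-to-moisture calibration.
#'
#' @param b a [batch_record()].
#' @param mode `"high_extreme"` or `"low_extreme"`.
#' @param magnitude shift size in campaign-SD units (>= 0).
#' @param param_sds named per-parameter SDs of the clean campaign rows; any
#'   parameter absent from it is left unshifted.
#' @param seed seed for the (small) stochastic part of the distortion.
#' @param slope_gain wavelength-slope distortion per SD of magnitude.
#' @param band_gain scaling of the water-band-response distortion relative
#'   to the clean moisture response.
#' @return the corrupted `batch_record`.
#' @export
inject_outlier_batch <- function(b, mode = c("high_extreme", "low_extreme"),
                                 magnitude = 3, param_sds, seed = 1L,
                                 slope_gain = 0.06, band_gain = 1) {
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (magnitude == 0) return(b)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sign <- if (mode == "high_extreme") 1 else -1
  shift <- intersect(OUTLIER_SHIFT_PARAMS, colnames(b$params))
  for (p in shift) {
    if (!p %in% names(param_sds)) next
    b$params[, p] <- b$params[, p] + sign * magnitude * param_sds[[p]]
  }
  wl01 <- seq(0, 1, length.out = ncol(b$spectra))
  offset <- sign * magnitude * 0.02
  slope <- sign * magnitude * slope_gain
  b$spectra <- b$spectra + outer(rep(1, nrow(b$spectra)),
                                 offset + slope * (wl01 - 0.5))
  # disturb the moisture-band response so the batch also breaks a pooled
  # spectra -> LOD calibration, not just the parameter cloud
  grid <- spectral_grid()
  water <- gaussian_band(grid, 1450, 45) + gaussian_band(grid, 1934, 45)
  lod_proxy <- rep(mean(b$lod$value), nrow(b$spectra))
  if (nrow(b$lod) >= 2L)
    lod_proxy <- stats::approx(b$lod$row, b$lod$value,
                               xout = seq_len(nrow(b$spectra)),
                               rule = 2L)$y
  b$spectra <- b$spectra +
    sign * band_gain * magnitude * 0.03 * outer(lod_proxy, water)
  validate_batch_record(b)
  b
}
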