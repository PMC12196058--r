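# Modeling-approach evaluation: within-batch endpoint prediction (the
# first 90% of a batch predicting its last 10%), drying-phase endpoint
# prediction, and across-batch prediction with 9->3, 11->1 and 8->4 batch
# folds; three predictor sets (NIR-only, parameters-only, merged); paired
# model comparison; regression-coefficient importance; and the sparse
# moisture (LOD) hold-out model.

#' Within-batch endpoint split (MA 1)
#'
#' The last `floor(n/10)` rows in time order form the external test set.
#' Within the remaining leading rows, every 10th row (positions 10, 20, ...)
#' is the sequential internal test set and the rest train the model. The
#' three sets are disjoint and exhaustive.
#'
#' @param b a [batch_record()], or an integer row count.
#' @return list of class `split_plan` with integer index vectors `train`,
#'   `internal_test`, `external_test`.
#' @export
ma1_split <- function(b) {
  n <- if (inherits(b, "batch_record")) length(b$times) else as.integer(b)
  if (n < 20L) stop("need at least 20 rows for an endpoint split",
                    call. = FALSE)
  n_ext <- n %/% 10L
  external <- seq.int(n - n_ext + 1L, n)
  lead <- seq_len(n - n_ext)
  internal <- lead[lead %% 10L == 0L]
  structure(list(train = setdiff(lead, internal), internal_test = internal,
                 external_test = external, scheme = "ma1", n = n),
            class = "split_plan")
}

#' Drying-phase endpoint split (MA 1-add)
#'
#' The external test set is the last half (floor) of the batch's final
#' maximal run of zero-spray (drying) rows; the remaining leading rows are
#' split 9/10 train, 1/10 sequential internal test as in [ma1_split()].
#'
#' @param b a [batch_record()].
#' @return a `split_plan`.
#' @export
ma1add_split <- function(b) {
  stopifnot(inherits(b, "batch_record"))
  n <- length(b$times)
  dry <- b$phase == "drying"
  if (!any(dry)) stop("batch '", b$batch_id, "' has no zero-spray rows",
                      call. = FALSE)
  if (!dry[n]) stop("batch '", b$batch_id, "' ends mid-spray: no terminal ",
                    "drying run", call. = FALSE)
  run_start <- max(which(!dry), 0L) + 1L
  run_len <- n - run_start + 1L
  n_ext <- run_len %/% 2L
  if (n_ext < 1L) stop("terminal drying run too short", call. = FALSE)
  external <- seq.int(n - n_ext + 1L, n)
  lead <- seq_len(n - n_ext)
  internal <- lead[lead %% 10L == 0L]
  structure(list(train = setdiff(lead, internal), internal_test = internal,
                 external_test = external, scheme = "ma1add", n = n),
            class = "split_plan")
}

#' Block cross-validation plan over training rows
#'
#' Contiguous (near-)equal blocks, the CV scheme that respects time order
#' in autocorrelated batch data; any remainder is spread over the leading
#' blocks.
#'
#' @param n number of training rows.
#' @param k block count (>= 2).
#' @return a [cv_plan()] with scheme `block_k`.
#' @export
block_cv_plan <- function(n, k) {
  cv_plan("block_k", n, k)
}

#' Across-batch fold assignment (MA 2)
#'
#' Partitions the batch ids, in campaign order, into test groups of
#' `test_size` so that every batch is predicted exactly once; the other
#' `train_size` batches train each fold. `test_size = 1` is
#' leave-one-batch-out.
#'
#' @param ids batch ids (in campaign order).
#' @param train_size,test_size group sizes; must sum to `length(ids)` and
#'   `test_size` must divide it.
#' @return list of folds, each with `train` and `test` id vectors.
#' @export
ma2_folds <- function(ids, train_size, test_size) {
  n <- length(ids)
  if (train_size + test_size != n)
    stop("train_size + test_size must equal the ", n, " batches",
         call. = FALSE)
  if (n %% test_size != 0L)
    stop(n, " batches cannot be grouped into test sets of ", test_size,
         "; drop ", n %% test_size, " batch(es) or change test_size",
         call. = FALSE)
  lapply(seq_len(n %/% test_size), function(j) {
    test <- ids[seq.int((j - 1L) * test_size + 1L, j * test_size)]
    list(train = setdiff(ids, test), test = test)
  })
}

# Build the predictor matrix for one predictor set from pooled raw blocks.
predictor_matrix <- function(spectra, params, set,
                             include_spray_rate = FALSE) {
  if (!include_spray_rate && "spray_rate" %in% colnames(params))
    params <- params[, setdiff(colnames(params), "spray_rate"),
                     drop = FALSE]
  if (include_spray_rate && "spray_rate" %in% colnames(params))
    params[, "spray_rate"] <- moving_average(params[, "spray_rate"], 7L)
  switch(set,
    nir = snv(spectra),
    pars = params,
    merged = cbind(snv(spectra), params),
    stop("unknown predictor set: ", set, call. = FALSE))
}

batch_design <- function(b, target) {
  if (!target %in% SIZE_COLUMNS)
    stop("unknown target column: ", target, call. = FALSE)
  list(spectra = b$spectra, params = b$params,
       y = b$sizes[, match(target, SIZE_COLUMNS)])
}

#' Reference statistics for a campaign target
#'
#' Population statistics of a granule-size target over all rows of the
#' non-excluded batches, with the laboratory error taken as the SD of the
#' per-batch endpoint (last-row) values.
#'
#' @param c a [campaign()].
#' @param target size column, e.g. `"dv50"`.
#' @param exclude batch ids to leave out (e.g. flagged outliers).
#' @return a [make_reference_stats()] object.
#' @export
campaign_reference_stats <- function(c, target = "dv50",
                                     exclude = character(0L)) {
  keep <- setdiff(batch_ids(c), exclude)
  pooled <- pool_rows(c, which = keep, columns = target)
  endpoints <- vapply(c$batches[keep], function(b) {
    b$sizes[nrow(b$sizes), match(target, SIZE_COLUMNS)]
  }, numeric(1L))
  make_reference_stats(as.numeric(pooled$x), lab_error = stats::sd(endpoints))
}

eval_one_split <- function(spectra, params, y, split, set,
                           include_spray_rate, max_lv, cv_k, ref_stats,
                           cv_scheme = "sequential_k") {
  X <- predictor_matrix(spectra, params, set, include_spray_rate)
  tr <- split$train
  plan <- cv_plan(cv_scheme, length(tr), k = cv_k)
  n_lv <- select_n_lv(X[tr, , drop = FALSE], y[tr], plan, max_lv = max_lv)
  cvr <- cross_validate(X[tr, , drop = FALSE], y[tr], plan, n_lv)
  fit <- fit_pls(X[tr, , drop = FALSE], y[tr], n_lv)
  ext <- split$external_test
  met <- prediction_metrics(y[ext], predict(fit, X[ext, , drop = FALSE]),
                            ref_stats)
  internal <- if (length(split$internal_test)) {
    it <- split$internal_test
    prediction_metrics(y[it], predict(fit, X[it, , drop = FALSE]))
  } else NULL
  list(n_lv = n_lv, rmsecv = cvr$rmsecv, fit = fit, external = met,
       internal = internal)
}

#' Run a modeling-approach comparison across predictor sets
#'
#' Evaluates one modeling approach over a campaign for each requested
#' predictor set and target. For within-batch approaches (`ma1`,
#' `ma1add`) every batch predicts its own endpoint; for across-batch
#' approaches (`ma2a`: 3-batch test groups, `ma2b`: leave-one-batch-out,
#' `ma2c`: 4-batch test groups) pooled training batches predict whole held
#' -out batches. The latent-variable count is selected per fit by
#' cross-validated RMSECV on the training rows only; test rows never touch
#' scaling, selection or coefficients.
#'
#' @param c a [campaign()].
#' @param approach one of `"ma1"`, `"ma1add"`, `"ma2a"`, `"ma2b"`,
#'   `"ma2c"`.
#' @param predictor_sets subset of `"nir"`, `"pars"`, `"merged"`.
#' @param targets granule-size columns to model.
#' @param exclude batch ids to drop before modeling (flagged outliers).
#' @param include_spray_rate add the 7-point moving-average spray rate as
#'   an 18th parameter?
#' @param max_lv latent-variable search cap.
#' @param cv_k fold count of the selection CV.
#' @param cv_scheme selection CV scheme (`"sequential_k"` or `"block_k"`).
#' @param keep_models keep fitted merged-set models (for
#'   [coefficient_importance()])?
#' @return object of class `eval_report`: `results` tibble (one row per
#'   batch x predictor set x target with n_lv, RMSECV, external RMSEP/R2,
#'   internal RMSEP and ratio metrics), `reference`, `approach`, `models`.
#' @export
run_comparison <- function(c, approach = c("ma1", "ma1add", "ma2a", "ma2b",
                                           "ma2c"),
                           predictor_sets = c("nir", "merged"),
                           targets = "dv50", exclude = character(0L),
                           include_spray_rate = FALSE, max_lv = 10L,
                           cv_k = 10L, cv_scheme = "sequential_k",
                           keep_models = FALSE) {
  approach <- match.arg(approach)
  ids <- setdiff(batch_ids(c), exclude)
  rows <- list()
  models <- list()
  for (target in targets) {
    ref <- campaign_reference_stats(c, target, exclude = exclude)
    if (approach %in% c("ma1", "ma1add")) {
      for (id in ids) {
        b <- c$batches[[id]]
        split <- if (approach == "ma1") ma1_split(b) else ma1add_split(b)
        d <- batch_design(b, target)
        for (set in predictor_sets) {
          r <- eval_one_split(d$spectra, d$params, d$y, split, set,
                              include_spray_rate, max_lv, cv_k, ref,
                              cv_scheme)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            target = target, predictor_set = set, batch_id = id,
            fold = NA_integer_, n_lv = r$n_lv, rmsecv = r$rmsecv,
            rmsep = r$external$rmsep, r2_test = r$external$r2_test,
            rmsep_internal = r$internal$rmsep,
            rpd = r$external$rpd, rer = r$external$rer,
            prl = r$external$prl, rpiq = r$external$rpiq)
          if (keep_models && set == "merged")
            models[[length(models) + 1L]] <- r$fit
        }
      }
    } else {
      test_size <- switch(approach, ma2a = 3L, ma2b = 1L, ma2c = 4L)
      folds <- ma2_folds(ids, length(ids) - test_size, test_size)
      for (j in seq_along(folds)) {
        fold <- folds[[j]]
        tr_pool <- lapply(fold$train, function(id)
          batch_design(c$batches[[id]], target))
        spectra_tr <- do.call(rbind, lapply(tr_pool, `[[`, "spectra"))
        params_tr <- do.call(rbind, lapply(tr_pool, `[[`, "params"))
        y_tr <- unlist(lapply(tr_pool, `[[`, "y"), use.names = FALSE)
        for (set in predictor_sets) {
          X_tr <- predictor_matrix(spectra_tr, params_tr, set,
                                   include_spray_rate)
          plan <- cv_plan(cv_scheme, nrow(X_tr), k = cv_k)
          n_lv <- select_n_lv(X_tr, y_tr, plan, max_lv = max_lv)
          cvr <- cross_validate(X_tr, y_tr, plan, n_lv)
          fit <- fit_pls(X_tr, y_tr, n_lv)
          for (id in fold$test) {
            d <- batch_design(c$batches[[id]], target)
            X_te <- predictor_matrix(d$spectra, d$params, set,
                                     include_spray_rate)
            met <- prediction_metrics(d$y, predict(fit, X_te), ref)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              target = target, predictor_set = set, batch_id = id,
              fold = j, n_lv = n_lv, rmsecv = cvr$rmsecv,
              rmsep = met$rmsep, r2_test = met$r2_test,
              rmsep_internal = NA_real_, rpd = met$rpd, rer = met$rer,
              prl = met$prl, rpiq = met$rpiq)
          }
          if (keep_models && set == "merged")
            models[[length(models) + 1L]] <- fit
        }
      }
    }
  }
  structure(list(results = do.call(rbind, rows),
                 reference = campaign_reference_stats(
                   c, targets[1L], exclude = exclude),
                 approach = approach, models = models),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> approach ", x$approach, "\n", sep = "")
  agg <- stats::aggregate(rmsep ~ target + predictor_set, data = x$results,
                          FUN = mean)
  print(agg)
  invisible(x)
}

#' One-tailed paired comparison of per-batch RMSEPs
#'
#' Paired t-test of the alternative that model A's per-batch RMSEPs are
#' lower than model B's. Identical vectors carry no evidence either way
#' and return p = 0.5; a degenerate nonzero constant difference is an
#' error.
#'
#' @param rmsep_a,rmsep_b aligned per-batch RMSEP vectors.
#' @return p-value.
#' @export
paired_rmsep_test <- function(rmsep_a, rmsep_b) {
  if (length(rmsep_a) != length(rmsep_b) || length(rmsep_a) < 2L)
    stop("need two aligned vectors of length >= 2", call. = FALSE)
  d <- rmsep_a - rmsep_b
  if (all(d == 0)) return(0.5)
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: t-test degenerate",
         call. = FALSE)
  stats::t.test(rmsep_a, rmsep_b, paired = TRUE,
                alternative = "less")$p.value
}

#' Regression-coefficient importance of merged models
#'
#' Averages absolute scaled regression coefficients across fitted merged
#' models, splits them into the spectral block and the process-parameter
#' block, and reports the parameters ranked by importance together with
#' the spectral mean, SD and the `mean + 2 SD` margin above which a
#' wavelength counts as individually important.
#'
#' @param models list of [fit_pls()] models sharing one predictor layout
#'   (spectral columns followed by parameter columns).
#' @param paramset parameter column names (default: the canonical 17).
#' @return list of class `coef_importance` with `parameters` (tibble,
#'   decreasing), `nir_mean`, `nir_sd`, `nir_max`, `margin`,
#'   `wavelengths_above_margin`.
#' @export
coefficient_importance <- function(models, paramset = process_parameters()) {
  if (!length(models)) stop("need at least one fitted model", call. = FALSE)
  mats <- vapply(models, function(m) abs(m$coef_scaled),
                 numeric(length(models[[1L]]$coef_scaled)))
  avg <- rowMeans(as.matrix(mats))
  nm <- names(models[[1L]]$B)
  names(avg) <- nm
  is_par <- nm %in% paramset
  nir <- avg[!is_par]
  pars <- sort(avg[is_par], decreasing = TRUE)
  margin <- mean(nir) + 2 * stats::sd(nir)
  structure(
    list(parameters = tibble::tibble(parameter = names(pars),
                                     abs_coef = as.numeric(pars)),
         nir_mean = mean(nir), nir_sd = stats::sd(nir), nir_max = max(nir),
         margin = margin,
         wavelengths_above_margin = names(nir)[nir > margin]),
    class = "coef_importance"
  )
}

#' Sparse-moisture (LOD) hold-out model
#'
#' Pools the LOD rows of all batches in campaign order, assigns every 5th
#' row to the test set and the rest to training (a sequential one-fifth
#' hold-out), and fits an NIR-only PLS calibration of LOD from the SNV
#' spectra with leave-one-out selection of the latent-variable count.
#'
#' @param c a [campaign()].
#' @param exclude batch ids to drop first (e.g. flagged outliers).
#' @param max_lv latent-variable search cap.
#' @return list of class `lod_report` with `train`/`test` index vectors,
#'   `n_lv`, `rmsec`, `rmsecv`, `rmsep`, `r2_cal`, `r2_test`,
#'   `predictions`.
#' @export
lod_holdout <- function(c, exclude = character(0L), max_lv = 10L) {
  keep <- setdiff(batch_ids(c), exclude)
  d <- bbe_dataset(c, keep)
  n <- length(d$y)
  if (n < 5L) stop("need at least 5 LOD rows", call. = FALSE)
  test <- seq_len(n)[seq_len(n) %% 5L == 0L]
  train <- setdiff(seq_len(n), test)
  X_tr <- d$X[train, , drop = FALSE]
  y_tr <- d$y[train]
  plan <- cv_plan("loo", length(train))
  n_lv <- select_n_lv(X_tr, y_tr, plan,
                      max_lv = min(max_lv, length(train) - 2L))
  cvr <- cross_validate(X_tr, y_tr, plan, n_lv)
  fit <- fit_pls(X_tr, y_tr, n_lv)
  pred <- predict(fit, d$X[test, , drop = FALSE])
  met <- prediction_metrics(d$y[test], pred)
  structure(
    list(train = train, test = test, n_lv = n_lv, rmsec = fit$rmsec,
         rmsecv = cvr$rmsecv, rmsep = met$rmsep, r2_cal = fit$r2_cal,
         r2_test = met$r2_test,
         predictions = tibble::tibble(row = test, observed = d$y[test],
                                      predicted = pred)),
    class = "lod_report"
  )
}
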