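# PLS1 regression engine: model fitting on autoscaled predictors with an
# unscaled response, nested latent-variable paths, the three
# cross-validation schemes (leave-one-out, sequential k-fold, block k-fold)
# and the prediction-quality metric bundle (RMSE, R2, RPD, RER, PRL, RPIQ).

#' Fit a PLS1 regression model
#'
#' Fits `Y = XB + E` by non-iterative NIPALS for a single response. The
#' predictor block is autoscaled internally (column mean 0, sample SD 1)
#' with statistics learned from the supplied rows; the response is centered
#' but never scaled. The fit is deterministic and invariant to row
#' permutation.
#'
#' @param X numeric predictor matrix (rows = samples).
#' @param y numeric response vector.
#' @param n_lv number of latent variables, in
#'   `1..min(nrow(X) - 1, ncol(X))`.
#' @param scale autoscale predictor columns? (centering always happens).
#' @return object of class `pls_model` with the regression vector `B` and
#'   `intercept` on the original predictor scale, the scaled-space
#'   coefficients `coef_scaled`, the learned `scaling`, and calibration
#'   statistics (`fitted`, `rmsec`, `r2_cal`).
#' @export
fit_pls <- function(X, y, n_lv, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("X and y must have the same number of rows", call. = FALSE)
  lv_max <- min(nrow(X) - 1L, ncol(X))
  if (n_lv < 1L || n_lv > lv_max)
    stop("n_lv must lie in 1..", lv_max, " for this problem, got ", n_lv,
         call. = FALSE)
  scaling <- if (scale) fit_scaling(X) else
    structure(list(mean = colMeans(X), sd = rep(1, ncol(X)),
                   scaled = rep(TRUE, ncol(X)), targets_excluded = FALSE),
              class = "scaling_params")
  Xs <- apply_scaling(scaling, X)
  ybar <- mean(y)
  path <- pls1_path(Xs, y - ybar, as.integer(n_lv))
  n_eff <- ncol(path$B)
  b_scaled <- path$B[, n_eff]
  scl <- ifelse(scaling$scaled, scaling$sd, 1)
  b_orig <- b_scaled / scl
  # unscaled columns are not centered either, so only scaled columns
  # contribute their mean to the intercept
  intercept <- ybar - sum(ifelse(scaling$scaled, scaling$mean, 0) * b_orig)
  names(b_orig) <- colnames(X)
  fitted <- as.numeric(X %*% b_orig + intercept)
  m <- structure(
    list(n_lv = n_eff, B = b_orig, intercept = intercept,
         coef_scaled = b_scaled, scaling = scaling, y_mean = ybar,
         fitted = fitted,
         rmsec = sqrt(mean((y - fitted)^2)),
         r2_cal = 1 - sum((y - fitted)^2) / sum((y - ybar)^2),
         n_train = nrow(X)),
    class = "pls_model"
  )
  m
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_lv, " latent variables, ", length(x$B),
      " predictors, RMSEC = ", signif(x$rmsec, 4L), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Applies the stored regression vector to new rows; no refitting and no
#' rescaling beyond what is baked into `B` and the intercept.
#'
#' @param object a [fit_pls()] model.
#' @param newdata matrix with the same columns as the training predictors.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$B))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$B), call. = FALSE)
  as.numeric(newdata %*% object$B + object$intercept)
}

#' Cross-validation fold plans
#'
#' * `loo` — leave-one-out, one fold per row;
#' * `sequential_k` — row `i` goes to fold `((i - 1) mod k) + 1`, the
#'   interleaved split used for internal test sets;
#' * `block_k` — `k` contiguous blocks of (near-)equal size, the scheme that
#'   respects the time ordering of autocorrelated batch data (any remainder
#'   is spread over the leading blocks).
#'
#' @param scheme one of `"loo"`, `"sequential_k"`, `"block_k"`.
#' @param n number of rows.
#' @param k fold count (ignored for `loo`).
#' @return object of class `cv_plan` with the per-row `fold` assignment.
#' @export
cv_plan <- function(scheme = c("loo", "sequential_k", "block_k"), n,
                    k = 10L) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  k <- as.integer(k)
  fold <- switch(scheme,
    loo = seq_len(n),
    sequential_k = {
      if (k < 2L || k > n) stop("k must lie in 2..n", call. = FALSE)
      ((seq_len(n) - 1L) %% k) + 1L
    },
    block_k = {
      if (k < 2L || k > n) stop("k must lie in 2..n", call. = FALSE)
      sizes <- rep(n %/% k, k)
      r <- n %% k
      if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
      rep(seq_len(k), times = sizes)
    })
  structure(list(scheme = scheme, k = if (scheme == "loo") n else k,
                 fold = fold, n = n), class = "cv_plan")
}

check_plan <- function(plan, n, n_lv) {
  if (!inherits(plan, "cv_plan")) stop("plan must be a cv_plan",
                                       call. = FALSE)
  if (plan$n != n)
    stop("plan covers ", plan$n, " rows but data has ", n, call. = FALSE)
  tr_sizes <- n - tabulate(plan$fold)
  if (any(tr_sizes < n_lv + 1L))
    stop("a fold leaves fewer than n_lv + 1 = ", n_lv + 1L,
         " training rows", call. = FALSE)
}

# Cross-validated predictions for every component count 1..max_lv in one
# pass (the NIPALS path is nested, so each fold is fit once).
cv_prediction_path <- function(X, y, plan, max_lv, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  max_lv <- min(max_lv, ncol(X),
                min(nrow(X) - tabulate(plan$fold)) - 1L)
  check_plan(plan, nrow(X), max_lv)
  out <- pls1_cv(X, y, as.integer(plan$fold), as.integer(max_lv), scale)
  resid <- out$pred - y
  list(pred = out$pred, resid = resid,
       rmsecv = sqrt(colMeans(resid^2)),
       coefs = out$coefs, max_lv = max_lv)
}

#' Cross-validate a PLS model
#'
#' Every row is predicted by a model fit without its fold; scaling
#' statistics and the regression vector are re-learned inside each fold
#' from the training rows only.
#'
#' @param X,y data, row-aligned.
#' @param plan a [cv_plan()] covering all rows.
#' @param n_lv latent-variable count for the reported residuals.
#' @param scale autoscale predictors inside each fold?
#' @return list with `rmsecv`, per-row `residuals` and `predictions`, and
#'   `rmsecv_path` (RMSECV for 1..`n_lv` components).
#' @export
cross_validate <- function(X, y, plan, n_lv, scale = TRUE) {
  cp <- cv_prediction_path(X, y, plan, n_lv, scale = scale)
  if (cp$max_lv < n_lv)
    stop("n_lv = ", n_lv, " not reachable: folds support at most ",
         cp$max_lv, " components", call. = FALSE)
  list(rmsecv = cp$rmsecv[n_lv], residuals = cp$resid[, n_lv],
       predictions = cp$pred[, n_lv], rmsecv_path = cp$rmsecv)
}

#' Select the number of latent variables by minimum RMSECV
#'
#' Scans 1..`max_lv` and returns the smallest component count attaining the
#' global RMSECV minimum (parsimony tie-break within `tol`): both too few
#' and too many components degrade prediction, and on ties the smaller
#' model is preferred.
#'
#' @param X,y data.
#' @param plan a [cv_plan()].
#' @param max_lv largest count to try (capped at the problem bounds).
#' @param scale autoscale predictors inside folds?
#' @param tol tie tolerance on RMSECV.
#' @return integer component count.
#' @export
select_n_lv <- function(X, y, plan, max_lv = 20L, scale = TRUE,
                        tol = 1e-12) {
  cp <- cv_prediction_path(X, y, plan, max_lv, scale = scale)
  rmsecv <- cp$rmsecv
  which(rmsecv <= min(rmsecv) + tol)[1L]
}

#' Reference population statistics for ratio metrics
#'
#' @param values reference population of the target (e.g. all non-outlier
#'   Dv50 rows).
#' @param lab_error laboratory error; for granule sizes, the SD of
#'   per-batch endpoint values.
#' @return list of class `reference_stats` with `sd`, `min`, `max`,
#'   `range`, `iqr` (Q3 - Q1) and `lab_error`.
#' @export
make_reference_stats <- function(values, lab_error = NA_real_) {
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  structure(list(sd = stats::sd(values), min = min(values),
                 max = max(values), range = max(values) - min(values),
                 iqr = q[2L] - q[1L], lab_error = lab_error),
            class = "reference_stats")
}

#' Prediction-quality metric bundle
#'
#' Computes RMSEP and test R2 for a prediction set and, when reference
#' statistics are supplied, the standardized ratios
#' `RPD = SD/RMSEP`, `RER = range/RMSEP`, `PRL = RMSEP/lab error` and
#' `RPIQ = (Q3 - Q1)/RMSEP`.
#'
#' @param observed,predicted aligned numeric vectors.
#' @param reference_stats optional [make_reference_stats()] object.
#' @return list of class `metric_bundle`.
#' @export
prediction_metrics <- function(observed, predicted,
                               reference_stats = NULL) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must be aligned", call. = FALSE)
  rmsep <- sqrt(mean((observed - predicted)^2))
  r2 <- 1 - sum((observed - predicted)^2) /
    sum((observed - mean(observed))^2)
  out <- list(rmsep = rmsep, r2_test = r2, rpd = NA_real_, rer = NA_real_,
              prl = NA_real_, rpiq = NA_real_)
  if (!is.null(reference_stats)) {
    if (rmsep == 0)
      stop("RMSEP is zero: ratio metrics undefined", call. = FALSE)
    out$rpd <- reference_stats$sd / rmsep
    out$rer <- reference_stats$range / rmsep
    out$prl <- rmsep / reference_stats$lab_error
    out$rpiq <- reference_stats$iqr / rmsep
  }
  structure(out, class = "metric_bundle")
}
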