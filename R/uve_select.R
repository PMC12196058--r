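# Uninformative-variable elimination PLS (UVE-PLS): per-variable
# jackknife coefficient stabilities against appended noise variables, and
# an RMSECV-driven search over linearly incremented stability cutoffs.

append_noise <- function(X, n_noise, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  N <- matrix(stats::runif(nrow(X) * n_noise, 0, 1e-10), nrow(X), n_noise)
  colnames(N) <- paste0(".noise_", seq_len(n_noise))
  cbind(X, N)
}

#' UVE coefficient stabilities
#'
#' Appends `n_noise` uniform small-amplitude noise columns to the predictor
#' block, then computes for every variable (real and noise) the jackknife
#' stability `mean(b_j) / sd(b_j)` of its regression coefficient over the
#' cross-validation submodels. Autoscaling inside each fold puts the noise
#' variables on the same footing as real ones, so their stabilities
#' calibrate what "uninformative" looks like. A zero coefficient SD yields
#' signed infinity.
#'
#' @param X,y data.
#' @param plan a [cv_plan()]; its submodels are the jackknife replicates.
#' @param n_lv latent-variable count of the submodels.
#' @param n_noise number of appended noise variables (default: as many as
#'   real predictors).
#' @param seed seed for the noise block.
#' @return named numeric vector of stabilities for the real predictors
#'   followed by the `.noise_*` columns.
#' @export
uve_stabilities <- function(X, y, plan, n_lv, n_noise = ncol(X),
                            seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xa <- append_noise(X, n_noise, seed)
  check_plan(plan, nrow(Xa), n_lv)
  out <- pls1_cv(Xa, as.numeric(y), as.integer(plan$fold),
                 as.integer(n_lv), TRUE)
  b <- out$coefs  # p x K, scaled space
  mu <- rowMeans(b)
  sdv <- apply(b, 1L, stats::sd)
  stab <- ifelse(sdv == 0, sign(mu) * Inf, mu / sdv)
  names(stab) <- colnames(Xa)
  stab
}

#' UVE-PLS cutoff search
#'
#' Scans 20 linearly incremented stability cutoffs. The largest candidate
#' cutoff is, under the default strategy, the `(n_lv + 2)`-th largest
#' absolute stability over all variables (real and noise); the alternative
#' strategy uses the overall maximum. A cutoff of 0 (retain everything) is
#' always prepended so the unselected model stays a candidate. For every
#' cutoff the real variables at or above it are kept, the model is refit,
#' and its RMSECV recorded; the RMSECV-minimizing cutoff wins, with ties
#' going to the smaller cutoff. Cutoffs retaining no variables are skipped.
#'
#' @param X,y data.
#' @param plan a [cv_plan()].
#' @param n_lv latent-variable count.
#' @param n_noise,seed passed to [uve_stabilities()].
#' @param n_cutoffs number of linearly spaced cutoffs (besides 0).
#' @param cutoff_strategy `"nth_stability"` (default) or `"max_stability"`.
#' @return object of class `uve_result`: `stability`, `cutoffs_tried`,
#'   `rmsecv_at_cutoff`, `chosen_cutoff`, `retained` (logical mask over the
#'   real predictors).
#' @export
uve_select <- function(X, y, plan, n_lv, n_noise = ncol(X), seed = 1L,
                       n_cutoffs = 20L,
                       cutoff_strategy = c("nth_stability",
                                           "max_stability")) {
  cutoff_strategy <- match.arg(cutoff_strategy)
  X <- as.matrix(X)
  p <- ncol(X)
  stab <- uve_stabilities(X, y, plan, n_lv, n_noise = n_noise, seed = seed)
  astab <- abs(stab)
  afin <- astab[is.finite(astab)]
  top <- if (cutoff_strategy == "nth_stability") {
    k <- min(n_lv + 2L, length(afin))
    sort(afin, decreasing = TRUE)[k]
  } else max(afin)
  cutoffs <- c(0, seq(min(afin), top, length.out = n_cutoffs))
  real_astab <- astab[seq_len(p)]
  rmsecv <- rep(NA_real_, length(cutoffs))
  for (i in seq_along(cutoffs)) {
    keep <- real_astab >= cutoffs[i]
    if (!any(keep)) next  # cutoff retains nothing; skipped
    Xk <- X[, keep, drop = FALSE]
    lv <- min(n_lv, ncol(Xk))
    rmsecv[i] <- cv_prediction_path(Xk, y, plan, lv)$rmsecv[lv]
  }
  ok <- which(!is.na(rmsecv))
  best <- ok[which.min(rmsecv[ok])]  # which.min takes the first = smallest
  structure(
    list(stability = stab, cutoffs_tried = cutoffs,
         rmsecv_at_cutoff = rmsecv, chosen_cutoff = cutoffs[best],
         retained = stats::setNames(real_astab >= cutoffs[best],
                                    colnames(X))),
    class = "uve_result"
  )
}

#' @export
print.uve_result <- function(x, ...) {
  cat("<uve_result> cutoff ", signif(x$chosen_cutoff, 4L), ": ",
      sum(x$retained), "/", length(x$retained), " variables retained, ",
      "RMSECV ", signif(min(x$rmsecv_at_cutoff, na.rm = TRUE), 4L), "\n",
      sep = "")
  invisible(x)
}

#' Fit a PLS model on UVE-retained variables
#'
#' Selects the latent-variable count by minimum RMSECV, runs the UVE cutoff
#' search, and refits the final model on the retained real variables only —
#' the artificial noise block never enters the returned model.
#'
#' @param X,y data.
#' @param plan a [cv_plan()].
#' @param max_lv latent-variable search cap.
#' @param ... passed to [uve_select()].
#' @return list with `model` (a [fit_pls()] fit on the retained columns),
#'   `uve` (the [uve_select()] result) and `n_lv`.
#' @export
uve_pls_fit <- function(X, y, plan, max_lv = 10L, ...) {
  X <- as.matrix(X)
  n_lv <- select_n_lv(X, y, plan, max_lv = max_lv)
  uve <- uve_select(X, y, plan, n_lv, ...)
  Xk <- X[, uve$retained, drop = FALSE]
  model <- fit_pls(Xk, y, n_lv = min(n_lv, ncol(Xk)))
  list(model = model, uve = uve, n_lv = n_lv)
}
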