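# Spectral and predictor preprocessing: row-wise SNV on spectra, column
# autoscaling with train-only statistics, and the centered moving average
# used to smooth the spray-rate signal.

#' Standard normal variate (SNV) transform
#'
#' Centers each spectrum to mean 0 and scales it to sample SD 1 (n-1
#' denominator), removing additive offsets and multiplicative scatter. SNV
#' is idempotent and invariant to affine transforms `a + b*x` with `b > 0`.
#'
#' @param x numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return object of the same shape, SNV-corrected row-wise.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    if (any(sdv == 0))
      stop("constant spectrum in row ", which(sdv == 0)[1L],
           ": SNV undefined", call. = FALSE)
    return((x - mu) / sdv)
  }
  sdv <- stats::sd(x)
  if (is.na(sdv) || sdv == 0)
    stop("constant spectrum: SNV undefined", call. = FALSE)
  (x - mean(x)) / sdv
}

#' Learn column scaling parameters on training rows
#'
#' Computes per-column means and sample SDs on the training rows only.
#' Target columns named in `exclude` pass through unscaled (targets are
#' never scaled in supervised fitting). Zero-variance columns are an error,
#' not silently epsilon-fixed.
#'
#' @param rows numeric matrix of training rows.
#' @param exclude character vector of column names (or integer indices) to
#'   leave unscaled.
#' @return list of class `scaling_params` with `mean`, `sd`, `scaled`
#'   (logical per column) and `targets_excluded`.
#' @export
fit_scaling <- function(rows, exclude = character(0L)) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L)
    stop("need >= 2 training rows to learn scaling", call. = FALSE)
  p <- ncol(rows)
  scaled <- rep(TRUE, p)
  if (length(exclude)) {
    idx <- if (is.character(exclude)) match(exclude, colnames(rows))
    else as.integer(exclude)
    scaled[idx[!is.na(idx)]] <- FALSE
  }
  mu <- colMeans(rows)
  sdv <- apply(rows, 2L, stats::sd)
  bad <- which(scaled & sdv == 0)
  if (length(bad)) {
    nm <- if (!is.null(colnames(rows))) colnames(rows)[bad[1L]] else bad[1L]
    stop("zero-variance column '", nm, "' cannot be autoscaled",
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv, scaled = scaled,
                 targets_excluded = length(exclude) > 0L),
            class = "scaling_params")
}

#' @rdname fit_scaling
#' @param params a `scaling_params` object.
#' @export
apply_scaling <- function(params, rows) {
  rows <- as.matrix(rows)
  if (ncol(rows) != length(params$mean))
    stop("column count (", ncol(rows), ") does not match scaling parameters (",
         length(params$mean), ")", call. = FALSE)
  ctr <- ifelse(params$scaled, params$mean, 0)
  scl <- ifelse(params$scaled, params$sd, 1)
  sweep(sweep(rows, 2L, ctr, "-"), 2L, scl, "/")
}

#' Centered moving average
#'
#' Seven-point centered moving average by default (the smoothing applied to
#' the spray-rate signal before it is used as a predictor). At the series
#' edges the window truncates to the available points.
#'
#' @param series numeric vector.
#' @param window odd window length, `<= length(series)`.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(series, window = 7L) {
  n <- length(series)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window > n) stop("window (", window, ") exceeds series length (", n,
                       ")", call. = FALSE)
  h <- window %/% 2L
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
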