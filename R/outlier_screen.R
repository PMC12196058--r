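# Batch outlier diagnostics: PCA with a modified Kaiser rule for choosing
# the component count, Mahalanobis distances in PC-score space, SIMCA-style
# t-based p-values on squared distances, and the backward batch elimination
# PLS loop (BBE-PLS) on the sparse moisture (LOD) calibration.

#' Fit a PCA model with Kaiser scores
#'
#' Principal component analysis on autoscaled columns (for outlier work all
#' variables, targets included, are scaled so variances compare directly).
#' Component signs are fixed by making each loading's largest-magnitude
#' entry positive, so score plots are reproducible. Kaiser scores are
#' `n_variables * fraction of explained variance` per component (the
#' eigenvalues of the correlation matrix when all columns are scaled).
#'
#' @param rows numeric matrix (>= 2 rows).
#' @param scale_all autoscale every column before decomposition?
#' @return object of class `pca_model` with `loadings`, `scores`,
#'   `explained` (fractions summing to 1), `kaiser_scores`, `center`,
#'   `scale`.
#' @export
fit_pca <- function(rows, scale_all = TRUE) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  if (scale_all && any(apply(rows, 2L, stats::sd) == 0))
    stop("zero-variance column cannot be autoscaled for PCA", call. = FALSE)
  pc <- stats::prcomp(rows, center = TRUE, scale. = scale_all)
  flip <- apply(pc$rotation, 2L, function(v) {
    if (v[which.max(abs(v))] < 0) -1 else 1
  })
  pc$rotation <- sweep(pc$rotation, 2L, flip, "*")
  pc$x <- sweep(pc$x, 2L, flip, "*")
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  structure(
    list(loadings = pc$rotation, scores = pc$x, explained = frac,
         kaiser_scores = ncol(rows) * frac, eigenvalues = ev,
         center = pc$center,
         scale = if (scale_all) pc$scale else rep(1, ncol(rows)),
         n_variables = ncol(rows)),
    class = "pca_model"
  )
}

#' Choose the number of principal components
#'
#' Modified Kaiser rule: among components whose Kaiser score (variables
#' times explained-variance fraction) reaches `kaiser_threshold`, the
#' largest count `k` is kept for which the scree drop in log-eigenvalue
#' from `k` to `k + 1` exceeds the median of the later drops — i.e. the
#' last retained component must sit at a genuine scree elbow, which guards
#' against the strict Kaiser rule's tendency to keep components that clear
#' the threshold only marginally. Falls back to 1 when nothing qualifies.
#'
#' @param m a [fit_pca()] model, or a numeric vector of Kaiser scores.
#' @param kaiser_threshold minimum Kaiser score (default 1, the classical
#'   eigenvalue-above-average rule).
#' @param use_scree apply the scree-elbow condition? `FALSE` gives the
#'   strict Kaiser rule.
#' @return integer component count (>= 1).
#' @export
choose_n_pc <- function(m, kaiser_threshold = 1, use_scree = TRUE) {
  scores <- if (inherits(m, "pca_model")) m$kaiser_scores else as.numeric(m)
  scores <- scores[scores > 0]
  K <- length(scores)
  candidates <- which(scores >= kaiser_threshold)
  if (!length(candidates)) return(1L)
  if (!use_scree) return(max(candidates))
  drops <- -diff(log(scores))  # drop k -> k+1
  ok <- vapply(candidates, function(k) {
    later <- if (k < K - 1L) drops[(k + 1L):(K - 1L)] else numeric(0L)
    k <= K - 1L && length(later) >= 1L &&
      drops[k] > stats::median(later)
  }, logical(1L))
  if (!any(ok)) return(1L)
  as.integer(max(candidates[ok]))
}

#' Mahalanobis distances in PC-score space
#'
#' Distance of each row from the score centroid using the covariance of
#' the fitted scores over the first `n_pc` components. Rows beyond the
#' threshold (default 3) are flagged as outliers.
#'
#' @param m a [fit_pca()] model.
#' @param n_pc number of leading components to use.
#' @param rows optional new rows to project; default: the fitted rows.
#' @param threshold flagging threshold on the distance.
#' @return tibble with `distance` and `flagged`.
#' @export
mahalanobis_pc <- function(m, n_pc, rows = NULL, threshold = 3) {
  if (n_pc > ncol(m$scores))
    stop("n_pc exceeds the ", ncol(m$scores), " fitted components",
         call. = FALSE)
  S_fit <- m$scores[, seq_len(n_pc), drop = FALSE]
  S <- if (is.null(rows)) S_fit else {
    rows <- as.matrix(rows)
    Xs <- sweep(sweep(rows, 2L, m$center, "-"), 2L, m$scale, "/")
    Xs %*% m$loadings[, seq_len(n_pc), drop = FALSE]
  }
  V <- stats::cov(S_fit)
  if (any(diag(V) == 0) || det(V) <= 0)
    stop("singular score covariance: reduce n_pc", call. = FALSE)
  d <- sqrt(stats::mahalanobis(S, colMeans(S_fit), V))
  tibble::tibble(distance = d, flagged = d > threshold)
}

#' SIMCA-style membership p-values on squared distances
#'
#' One-tailed t-based p-value for each candidate row's membership in the
#' non-outlier reference population of squared distances:
#' `t = (d2 - mean_ref) / (sd_ref * sqrt(1 + 1/n_ref))` referred to a t
#' distribution with `n_ref - 1` degrees of freedom. A candidate at the
#' reference mean gets p = 0.5; p decreases monotonically as the candidate
#' moves above the reference.
#'
#' @param distances_sq per-row squared distances.
#' @param candidate indices of rows to test.
#' @param reference indices of the non-outlier reference rows (>= 3).
#' @return numeric p-values, one per candidate.
#' @export
simca_p <- function(distances_sq, candidate, reference) {
  ref <- distances_sq[reference]
  if (length(ref) < 3L)
    stop("reference set must hold at least 3 rows", call. = FALSE)
  s <- stats::sd(ref)
  if (s == 0) stop("zero-variance reference set", call. = FALSE)
  tval <- (distances_sq[candidate] - mean(ref)) / (s * sqrt(1 + 1 / length(ref)))
  stats::pt(tval, df = length(ref) - 1L, lower.tail = FALSE)
}

bbe_dataset <- function(c, which = NULL) {
  pooled <- pool_rows(c, which = which, columns = c("spectra", "lod"))
  X <- snv(pooled$x[, seq_len(256L), drop = FALSE])
  list(X = X, y = pooled$x[, "lod"], batch = pooled$provenance$batch_id)
}

# The one significance pairing used by BBE-PLS, isolated so the
# alternative pairing is a one-line change. The one-tailed equal-variance
# t-test compares squared cross-validated residuals of the full model with
# those of the reduced model on the rows both models predict (the rows of
# the candidate batch are excluded from the full-model sample): it asks
# whether removing the batch improves prediction of the remaining data.
# Including the candidate's own residuals in the full-model sample instead
# biases every cycle towards significance, because the argmin candidate is
# by construction the batch with the worst residuals.
bbe_significance <- function(full_common_resid, reduced_resid) {
  stats::t.test(full_common_resid^2, reduced_resid^2,
                alternative = "greater", var.equal = TRUE)$p.value
}

#' Backward batch elimination PLS (BBE-PLS)
#'
#' Screens whole batches against a pooled spectra-to-moisture (LOD)
#' calibration. Each cycle: (i) leave-one-out RMSECV over all remaining
#' rows; (ii) RMSECV with each batch removed in turn; (iii) the batch whose
#' removal gives the lowest RMSECV is eliminated if the one-tailed
#' equal-variance t-test on squared cross-validated residuals (full vs
#' reduced model over the rows both predict; see `bbe_significance` in the
#' source for the pairing) is significant at `alpha`;
#' (iv) repeat until the first non-significant cycle. The latent-variable
#' count is re-selected at the start of every cycle.
#'
#' @param c a [campaign()] whose batches carry LOD measurements.
#' @param alpha significance level (default 0.1).
#' @param max_lv latent-variable search cap.
#' @param min_batches hard stop: never eliminate below this many batches.
#' @return object of class `outlier_report`: `cycles` (tibble with the
#'   candidate, RMSECVs and p-value of every cycle, including the final
#'   non-significant one), `eliminated`, `surviving`, `n_lv` per cycle.
#' @export
bbe_pls <- function(c, alpha = 0.1, max_lv = 10L, min_batches = 2L) {
  ids <- batch_ids(c)
  if (length(ids) < 3L) stop("BBE-PLS needs at least 3 batches",
                             call. = FALSE)
  cycles <- list()
  eliminated <- character(0L)
  repeat {
    keep <- setdiff(ids, eliminated)
    d <- bbe_dataset(c, keep)
    plan <- cv_plan("loo", length(d$y))
    lv_cap <- min(max_lv, length(d$y) - 2L, ncol(d$X))
    n_lv <- select_n_lv(d$X, d$y, plan, max_lv = lv_cap)
    cv_full <- cross_validate(d$X, d$y, plan, n_lv)
    cand_rmsecv <- vapply(keep, function(b) {
      rows <- d$batch != b
      p2 <- cv_plan("loo", sum(rows))
      cross_validate(d$X[rows, , drop = FALSE], d$y[rows], p2,
                     min(n_lv, sum(rows) - 2L))$rmsecv
    }, numeric(1L))
    best <- keep[which.min(cand_rmsecv)]
    rows <- d$batch != best
    p2 <- cv_plan("loo", sum(rows))
    cv_red <- cross_validate(d$X[rows, , drop = FALSE], d$y[rows], p2,
                             min(n_lv, sum(rows) - 2L))
    pval <- bbe_significance(cv_full$residuals[rows], cv_red$residuals)
    cycles[[length(cycles) + 1L]] <- tibble::tibble(
      cycle = length(cycles) + 1L, candidate = best,
      rmsecv_before = cv_full$rmsecv,
      rmsecv_after = min(cand_rmsecv), p_value = pval, n_lv = n_lv,
      eliminated = pval < alpha && length(keep) > min_batches
    )
    if (!(pval < alpha) || length(keep) <= min_batches) break
    eliminated <- c(eliminated, best)
  }
  structure(
    list(cycles = do.call(rbind, cycles), eliminated = eliminated,
         surviving = setdiff(ids, eliminated)),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> eliminated: ",
      if (length(x$eliminated)) paste(x$eliminated, collapse = ", ")
      else "(none)", "; surviving: ", length(x$surviving), " batches\n",
      sep = "")
  print(x$cycles)
  invisible(x)
}

#' Full outlier screen: PCA + Mahalanobis + SIMCA + BBE-PLS
#'
#' Runs the whole diagnostic battery on the LOD rows of a campaign: PCA of
#' the SNV spectra (all columns scaled), component count by the modified
#' Kaiser rule, Mahalanobis distances over those components with the
#' flagging threshold, SIMCA p-values per batch against the unflagged
#' reference rows, and BBE-PLS. Batches eliminated by BBE-PLS are the
#' flagged outliers.
#'
#' @param c a [campaign()].
#' @param n_pc leading components for the distance screen (default 5; the
#'   [choose_n_pc()] rule is a diagnostic, but screening distances degrade
#'   as near-noise components enter, so the count is fixed and low here).
#' @param mahalanobis_threshold flagging threshold on the PC-space distance.
#' @param alpha BBE-PLS significance level.
#' @param max_lv BBE-PLS latent-variable cap.
#' @return list of class `outlier_screen` with `bbe` (the
#'   [bbe_pls()] report), `flagged_batches`, `n_pc`, `mahalanobis`
#'   (per-row tibble with batch provenance) and `simca` (per-batch tibble).
#' @export
outlier_screen <- function(c, n_pc = 5L, mahalanobis_threshold = 3,
                           alpha = 0.1, max_lv = 10L) {
  d <- bbe_dataset(c)
  pca <- fit_pca(cbind(d$X, lod = d$y), scale_all = TRUE)
  n_pc <- min(max(n_pc, 2L), ncol(pca$scores))
  mah <- mahalanobis_pc(pca, n_pc, threshold = mahalanobis_threshold)
  mah$batch_id <- d$batch
  ref <- which(!mah$flagged)
  simca <- tibble::tibble(
    batch_id = unique(d$batch),
    p_value = vapply(unique(d$batch), function(b) {
      stats::median(simca_p(mah$distance^2, which(d$batch == b), ref))
    }, numeric(1L))
  )
  bbe <- bbe_pls(c, alpha = alpha, max_lv = max_lv)
  structure(list(bbe = bbe, flagged_batches = bbe$eliminated, n_pc = n_pc,
                 mahalanobis = mah, simca = simca),
            class = "outlier_screen")
}
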