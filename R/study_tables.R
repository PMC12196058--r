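# Published reference results from a 14-batch fluid-bed granulation study
# (Dv50 population statistics, per-approach RMSEP tables, coefficient
# importances, UVE selection counts). These ship as plain-text tables and
# serve as worked-example inputs and as fixed inputs for consistency checks
# of the metric arithmetic; no claim beyond arithmetic on them is made.

#' Reference study tables
#'
#' Loads the bundled summary tables of a 14-batch granulation study:
#' * `dv50_reference` — Dv50 population statistics (SD, range, quartiles,
#'   lab error) for the two outlier batches and the pooled non-outliers;
#' * `ma1_rmsep` — within-batch endpoint RMSEP averages per target and
#'   predictor set, with and without the outlier batches;
#' * `ma2a_results`, `ma2b_results` — across-batch fold results (RMSECV,
#'   RMSEP, R2) for 9-predict-3 and leave-one-batch-out;
#' * `ratio_summary` — the published RPD/RER/PRL/RPIQ summary;
#' * `parameter_importance` — average absolute regression coefficients of
#'   the 16 listed process parameters;
#' * `uve_ma2a` — UVE-PLS per-fold RMSEP and selected-variable counts;
#' * `reported_values` — miscellaneous reported scalars (coefficient
#'   margin, internal-test errors, block-CV errors, LOD model errors).
#'
#' @return named list of tibbles.
#' @export
study_tables <- function() {
  dir <- system.file("extdata", "study_tables", package = "fbgpls",
                     mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  out <- lapply(files, readr::read_csv, show_col_types = FALSE,
                progress = FALSE)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Ratio-metric row from an RMSEP and reference statistics
#'
#' @param rmsep prediction error (um).
#' @param ref a [make_reference_stats()] object or a one-row table with
#'   `st_dev`, `range`, `lab_error`, `q3_q1` columns.
#' @return tibble with `rpd`, `rer`, `prl`, `rpiq`.
#' @export
ratio_metrics_row <- function(rmsep, ref) {
  if (inherits(ref, "reference_stats")) {
    ref <- tibble::tibble(st_dev = ref$sd, range = ref$range,
                          lab_error = ref$lab_error, q3_q1 = ref$iqr)
  }
  tibble::tibble(rpd = ref$st_dev / rmsep, rer = ref$range / rmsep,
                 prl = rmsep / ref$lab_error, rpiq = ref$q3_q1 / rmsep)
}

#' Recompute the ratio-metric summary from the study tables
#'
#' Rebuilds the RPD/RER/PRL/RPIQ summary from the non-outlier Dv50
#' reference statistics and the per-approach RMSEPs: the within-batch
#' (`ma1`) non-outlier averages, the mean across-batch fold RMSEPs, and for
#' the merged 9-predict-3 row the reported average RMSEP (the per-fold
#' table mean differs from it by 0.25 um; both are returned).
#'
#' @param tables output of [study_tables()].
#' @return tibble with one row per approach x model, computed columns
#'   `rpd`, `rer`, `prl`, `rpiq` and the `rmsep` used.
#' @export
recompute_ratio_summary <- function(tables = study_tables()) {
  ref <- tables$dv50_reference[tables$dv50_reference$group ==
                                 "non_outliers", ]
  rv <- tables$reported_values
  val <- function(nm) rv$value[rv$name == nm]
  ma1 <- tables$ma1_rmsep[tables$ma1_rmsep$target == "dv50", ]
  rows <- tibble::tibble(
    approach = c("ma1", "ma1", "ma2a", "ma2a", "ma2a", "ma2b", "ma2b"),
    model = c("nir", "merged", "nir", "merged", "merged_fold_mean",
              "nir", "merged"),
    rmsep = c(ma1$nir_nonoutlier, ma1$merged_nonoutlier,
              mean(tables$ma2a_results$nir_rmsep),
              val("ma2a_merged_rmsep_avg"),
              mean(tables$ma2a_results$merged_rmsep),
              mean(tables$ma2b_results$nir_rmsep),
              mean(tables$ma2b_results$merged_rmsep))
  )
  cbind(rows, ratio_metrics_row(rows$rmsep, ref))
}
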