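# Batch campaign data model: aligned NIR spectra, process parameters and
# granule-size percentiles for fluidized-bed granulation runs, plus the
# delimited-text interchange format every other module consumes.

SIZE_COLUMNS <- c("dv10", "dv25", "dv50", "dv75", "dv90")

#' Canonical process-parameter names
#'
#' The seventeen fluid-bed process parameters recorded alongside each NIR
#' acquisition: airflow rate (m3/h), runtime (s), atomizing pressure (bar),
#' inlet/exhaust/product temperatures (deg C), plenum and exhaust pressures,
#' and the PHT (pressure-humidity-temperature) probe channels at the inlet
#' and outlet air points. Spray rate (g/min) can be appended as an optional
#' eighteenth predictor.
#'
#' @param include_spray_rate append `spray_rate` as an 18th name?
#' @return character vector of canonical parameter identifiers, in the fixed
#'   column order used throughout the package.
#' @export
process_parameters <- function(include_spray_rate = FALSE) {
  nm <- c(
    "airflow_rate", "runtime", "atomizing_pressure", "pht_out_temp",
    "inlet_air_temp", "plenum_pressure", "exhaust_pressure",
    "pht_in_abs_hum", "pht_in_rel_hum", "pht_out_rel_hum",
    "pht_out_abs_hum", "exhaust_temp", "pht_out_pressure", "product_temp",
    "pht_in_pressure", "prod_filt_diff_pressure", "pht_in_temp"
  )
  if (include_spray_rate) nm <- c(nm, "spray_rate")
  nm
}

#' Spectral grid for the NIR channel axis
#'
#' @param wavelengths_nm strictly increasing vector of exactly 256
#'   wavelengths within 1081-2122 nm. The default is the evenly spaced grid
#'   over the full instrument range.
#' @return numeric vector of class `spectral_grid`.
#' @export
spectral_grid <- function(wavelengths_nm = default_wavelengths()) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != 256L)
    stop("spectral grid must hold exactly 256 wavelengths, got ",
         length(wavelengths_nm), call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("spectral grid must be strictly increasing", call. = FALSE)
  if (min(wavelengths_nm) < 1081 || max(wavelengths_nm) > 2122)
    stop("spectral grid must lie within 1081-2122 nm", call. = FALSE)
  structure(wavelengths_nm, class = "spectral_grid")
}

#' @rdname spectral_grid
#' @export
default_wavelengths <- function() {
  round(seq(1081, 2122, length.out = 256L), 4)
}

wavelength_colnames <- function(grid) {
  sprintf("%.10g", as.numeric(grid))
}

#' Construct a single-batch record
#'
#' A `batch_record` holds one granulation run as aligned row-wise time
#' series: NIR absorbance spectra, process parameters, the five granule-size
#' percentiles (Dv10..Dv90, um) and sparse loss-on-drying (LOD, %) moisture
#' measurements. Rows are acquisition instants; the `phase` label separates
#' the binder-spraying phase from the terminal drying phase.
#'
#' @param batch_id character label, e.g. `"1005"`.
#' @param times monotone non-decreasing acquisition times in seconds.
#' @param spectra n x 256 absorbance matrix on the campaign grid.
#' @param params n x 17 (or 18) matrix, columns ordered per
#'   [process_parameters()].
#' @param sizes n x 5 matrix of Dv10, Dv25, Dv50, Dv75, Dv90 (um).
#' @param lod data frame with columns `row` (1-based index) and `value`
#'   (LOD %), possibly empty.
#' @param phase character vector in `{"spray", "drying"}`, one per row.
#' @return object of class `batch_record`.
#' @export
batch_record <- function(batch_id, times, spectra, params, sizes,
                         lod = NULL, phase) {
  spectra <- as.matrix(spectra)
  params <- as.matrix(params)
  sizes <- as.matrix(sizes)
  if (is.null(lod)) lod <- data.frame(row = integer(), value = numeric())
  b <- structure(
    list(batch_id = as.character(batch_id), times = as.numeric(times),
         spectra = spectra, params = params, sizes = sizes,
         lod = lod, phase = as.character(phase)),
    class = "batch_record"
  )
  validate_batch_record(b)
  b
}

#' @rdname batch_record
#' @param b a `batch_record`.
#' @export
validate_batch_record <- function(b) {
  n <- length(b$times)
  id <- b$batch_id
  if (nrow(b$spectra) != n || nrow(b$params) != n || nrow(b$sizes) != n ||
      length(b$phase) != n)
    stop("batch '", id, "': spectra, params, sizes and phase must all have ",
         n, " rows", call. = FALSE)
  if (ncol(b$spectra) != 256L)
    stop("batch '", id, "': spectra must have 256 columns", call. = FALSE)
  if (!ncol(b$params) %in% c(17L, 18L))
    stop("batch '", id, "': params must have 17 or 18 columns", call. = FALSE)
  if (ncol(b$sizes) != 5L)
    stop("batch '", id, "': sizes must have 5 columns (Dv10..Dv90)",
         call. = FALSE)
  if (is.unsorted(b$times))
    stop("batch '", id, "': times must be non-decreasing", call. = FALSE)
  if (any(b$sizes <= 0))
    stop("batch '", id, "': granule sizes must be positive", call. = FALSE)
  bad <- which(apply(b$sizes, 1L, is.unsorted))
  if (length(bad))
    stop("batch '", id, "': Dv percentiles out of order ",
         "(Dv10 <= Dv25 <= Dv50 <= Dv75 <= Dv90 violated) at row ", bad[1L],
         call. = FALSE)
  if (!all(b$phase %in% c("spray", "drying")))
    stop("batch '", id, "': phase labels must be 'spray' or 'drying'",
         call. = FALSE)
  if (nrow(b$lod)) {
    if (any(b$lod$row < 1L | b$lod$row > n))
      stop("batch '", id, "': LOD row index out of range", call. = FALSE)
    if (any(b$lod$value < 0 | b$lod$value > 100))
      stop("batch '", id, "': LOD must lie in [0, 100] %", call. = FALSE)
  }
  if ("spray_rate" %in% colnames(b$params)) {
    sr <- b$params[, "spray_rate"]
    if (any((sr == 0) != (b$phase == "drying")))
      stop("batch '", id, "': drying phase must coincide with zero spray ",
           "rate", call. = FALSE)
  }
  invisible(b)
}

#' @export
print.batch_record <- function(x, ...) {
  cat("<batch_record '", x$batch_id, "'> ", length(x$times), " rows, ",
      ncol(x$params), " parameters, ", nrow(x$lod), " LOD points; phases: ",
      sum(x$phase == "spray"), " spray / ", sum(x$phase == "drying"),
      " drying\n", sep = "")
  invisible(x)
}

#' Construct a campaign of batches
#'
#' A `campaign` bundles several batch records that share one spectral grid
#' and one process-parameter set, mirroring a granulation study run as a
#' series of batches on the same unit.
#'
#' @param batches list of [batch_record()] objects with unique ids.
#' @param grid [spectral_grid()] shared by all batches.
#' @param paramset character vector of canonical parameter names shared by
#'   all batches.
#' @return object of class `campaign`.
#' @export
campaign <- function(batches, grid = spectral_grid(),
                     paramset = process_parameters()) {
  ids <- vapply(batches, function(b) b$batch_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate batch ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  for (b in batches) {
    if (!identical(colnames(b$params), paramset))
      stop("batch '", b$batch_id, "': parameter columns do not match the ",
           "campaign parameter set", call. = FALSE)
  }
  names(batches) <- ids
  structure(list(batches = batches, grid = grid, paramset = paramset),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat("<campaign> ", length(x$batches), " batches, ",
      sum(vapply(x$batches, function(b) length(b$times), numeric(1L))),
      " rows total, ", length(x$paramset), " process parameters\n", sep = "")
  invisible(x)
}

#' @rdname campaign
#' @param c a `campaign`.
#' @export
batch_ids <- function(c) names(c$batches)

batch_table <- function(b, grid) {
  lodcol <- rep(NA_real_, length(b$times))
  lodcol[b$lod$row] <- b$lod$value
  d <- data.frame(time = b$times, phase = b$phase, check.names = FALSE)
  d <- cbind(d, as.data.frame(b$params),
             stats::setNames(as.data.frame(b$sizes), SIZE_COLUMNS),
             lod = lodcol,
             stats::setNames(as.data.frame(b$spectra),
                             wavelength_colnames(grid)))
  tibble::as_tibble(d)
}

table_to_batch <- function(d, batch_id, grid, paramset) {
  need <- c("time", "phase", paramset, SIZE_COLUMNS, "lod")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("batch '", batch_id, "': missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  wl <- wavelength_colnames(grid)
  missing_wl <- setdiff(wl, names(d))
  if (length(missing_wl))
    stop("batch '", batch_id, "': missing wavelength column(s), e.g. ",
         missing_wl[1L], call. = FALSE)
  lod_rows <- which(!is.na(d$lod))
  batch_record(
    batch_id = batch_id,
    times = d$time,
    spectra = as.matrix(d[wl]),
    params = as.matrix(d[paramset]),
    sizes = as.matrix(d[SIZE_COLUMNS]),
    lod = data.frame(row = lod_rows, value = d$lod[lod_rows]),
    phase = d$phase
  )
}

#' Write a campaign to a directory of delimited text tables
#'
#' Emits one UTF-8 comma-delimited table per batch (wavelength columns named
#' by their nm value) plus a `campaign.yml` manifest listing batch ids, the
#' spectral grid and the parameter set. Numeric values round-trip at full
#' double precision.
#'
#' @param c a [campaign()].
#' @param path directory to create/write into.
#' @return invisibly, the vector of files written.
#' @export
write_campaign <- function(c, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  files <- character(0L)
  for (b in c$batches) {
    f <- file.path(path, paste0("batch_", b$batch_id, ".csv"))
    readr::write_csv(batch_table(b, c$grid), f, progress = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    batch_ids = as.list(batch_ids(c)),
    files = as.list(basename(files)),
    wavelengths_nm = as.numeric(c$grid),
    parameters = as.list(c$paramset)
  )
  mf <- file.path(path, "campaign.yml")
  yaml::write_yaml(manifest, mf, precision = 15L)
  invisible(c(files, mf))
}

#' Read a campaign from a directory written by [write_campaign()]
#'
#' @param path directory holding per-batch tables and `campaign.yml`.
#' @return a [campaign()].
#' @export
read_campaign <- function(path) {
  mf <- file.path(path, "campaign.yml")
  if (!file.exists(mf))
    stop("no campaign manifest found at ", mf, call. = FALSE)
  manifest <- yaml::read_yaml(mf)
  grid <- spectral_grid(as.numeric(manifest$wavelengths_nm))
  paramset <- as.character(unlist(manifest$parameters))
  ids <- as.character(unlist(manifest$batch_ids))
  files <- file.path(path, as.character(unlist(manifest$files)))
  batches <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    # base parser: correctly rounded doubles, so write/read is bit-exact
    d <- utils::read.csv(files[i], check.names = FALSE,
                         stringsAsFactors = FALSE)
    batches[[i]] <- table_to_batch(d, ids[i], grid, paramset)
  }
  campaign(batches, grid = grid, paramset = paramset)
}

#' Pool rows across batches with provenance
#'
#' Concatenates the selected blocks of the selected batches into one matrix,
#' batch order then time order, and returns a provenance table mapping every
#' pooled row back to its `(batch_id, row_index)` origin.
#'
#' @param c a [campaign()].
#' @param which batch ids to pool (default: all).
#' @param columns any of `"spectra"`, `"params"`, `"sizes"`, `"time"`,
#'   a size column (`"dv50"`, ...), or `"lod"` (sparse; restricts pooled rows
#'   to those carrying an LOD value).
#' @return list with elements `x` (matrix), `provenance` (tibble with
#'   `batch_id`, `row_index`).
#' @export
pool_rows <- function(c, which = NULL,
                      columns = c("spectra", "params", "sizes")) {
  if (is.null(which)) which <- batch_ids(c)
  unknown <- setdiff(which, batch_ids(c))
  if (length(unknown))
    stop("unknown batch id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lod_only <- "lod" %in% columns
  pieces <- vector("list", length(which))
  prov <- vector("list", length(which))
  for (i in seq_along(which)) {
    b <- c$batches[[which[i]]]
    rows <- if (lod_only) b$lod$row else seq_along(b$times)
    blocks <- list()
    for (col in columns) {
      blk <- switch(col,
        spectra = b$spectra[rows, , drop = FALSE],
        params = b$params[rows, , drop = FALSE],
        sizes = b$sizes[rows, , drop = FALSE],
        time = matrix(b$times[rows], ncol = 1L,
                      dimnames = list(NULL, "time")),
        lod = matrix(b$lod$value, ncol = 1L, dimnames = list(NULL, "lod")),
        {
          if (!col %in% SIZE_COLUMNS)
            stop("unknown column selector: ", col, call. = FALSE)
          matrix(b$sizes[rows, match(col, SIZE_COLUMNS)], ncol = 1L,
                 dimnames = list(NULL, col))
        })
      blocks[[col]] <- blk
    }
    pieces[[i]] <- do.call(cbind, blocks)
    prov[[i]] <- tibble::tibble(batch_id = b$batch_id, row_index = rows)
  }
  list(x = do.call(rbind, pieces), provenance = do.call(rbind, prov))
}
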