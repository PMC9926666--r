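# Long-form CSV IO for spectra and offline sample tables.
#
# Canonical spectra format: one row per pixel with columns
# well, time_h, ex_nm, em_nm, intensity, sorted by (well, time, ex, em).
# Floats are written with "%.17g" so doubles round-trip exactly.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write spectrum series to long-form CSV
#'
#' Writes one row per valid pixel in canonical order (well, time,
#' excitation, emission) at full floating-point precision, so that
#' `read_eem_series()` followed by `write_eem_series()` reproduces the file
#' byte for byte.
#'
#' @param series A list of `spectrum_series` (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eem_series <- function(series, path) {
  if (inherits(series, "spectrum_series")) series <- list(series)
  chunks <- vector("list", 0L)
  for (s in series) {
    for (m in s$measurements) {
      g <- m$grid
      keep <- which(m$valid)  # column-major over (ex, em)
      if (length(keep) == 0L) next
      ex_i <- ((keep - 1L) %% nrow(m$valid)) + 1L
      em_j <- ((keep - 1L) %/% nrow(m$valid)) + 1L
      chunks[[length(chunks) + 1L]] <- data.table::data.table(
        well = s$well_id,
        time = m$time,
        ex = g$excitation[ex_i],
        em = g$emission[em_j],
        intensity = m$intensities[keep]
      )
    }
  }
  if (length(chunks) == 0L) {
    dt <- data.table::data.table(well = character(), time_h = character(),
                                 ex_nm = character(), em_nm = character(),
                                 intensity = character())
    data.table::fwrite(dt, path)
    return(invisible(path))
  }
  dt <- data.table::rbindlist(chunks)
  data.table::setorder(dt, well, time, ex, em)
  out <- data.table::data.table(
    well = dt$well,
    time_h = fmt_full(dt$time),
    ex_nm = fmt_full(dt$ex),
    em_nm = fmt_full(dt$em),
    intensity = fmt_full(dt$intensity)
  )
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read spectrum series from long-form CSV
#'
#' Expects columns `well, time_h, ex_nm, em_nm, intensity`. The wavelength
#' grid is inferred from the union of pixels and validated: every
#' (well, time) must carry the complete grid, otherwise reading aborts
#' naming the first offending spectrum.
#'
#' @param path Input file path.
#' @param well_map Optional data.frame `well_id, condition_id` used to
#'   attach condition labels; unmapped wells get condition `NA`.
#' @param cadence Nominal cadence stored on each series, hours.
#' @return A list of `spectrum_series`, one per well, each sorted by time.
#' @export
read_eem_series <- function(path, well_map = NULL, cadence = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("well", "time_h", "ex_nm", "em_nm", "intensity")
  if (!all(need %in% names(dt)))
    stop("spectra file must have columns: ", paste(need, collapse = ", "))
  if (nrow(dt) == 0L) return(list())
  ex <- sort(unique(dt$ex_nm))
  em <- sort(unique(dt$em_nm))
  grid <- eem_grid(ex, em)
  n_px <- length(ex) * length(em)
  data.table::setorder(dt, well, time_h, ex_nm, em_nm)
  out <- list()
  for (w in unique(dt$well)) {
    dw <- dt[dt$well == w, ]
    times <- unique(dw$time_h)
    meas <- vector("list", length(times))
    for (k in seq_along(times)) {
      dk <- dw[dw$time_h == times[k], ]
      if (nrow(dk) != n_px ||
          anyDuplicated(dk[, c("ex_nm", "em_nm")]) > 0L)
        stop(sprintf("ragged grid: well %s at %g h has %d of %d pixels",
                     w, times[k], nrow(dk), n_px))
      mat <- matrix(NA_real_, length(ex), length(em))
      mat[cbind(match(dk$ex_nm, ex), match(dk$em_nm, em))] <- dk$intensity
      meas[[k]] <- eem_measurement(w, times[k], mat, grid,
                                   check_nonnegative = FALSE)
    }
    cond <- NA_character_
    if (!is.null(well_map)) {
      hit <- match(w, well_map$well_id)
      if (!is.na(hit)) cond <- as.character(well_map$condition_id[hit])
    }
    out[[w]] <- spectrum_series(w, cond, meas, cadence = cadence)
  }
  out
}

#' Offline reference sample table
#'
#' Wraps a data.frame of offline measurements (one row per condition and
#' sampling time) and classifies or records its sampling schedule. The
#' sparse schedule of the monitoring workflow has 6-8 samples per condition
#' with consecutive gaps of at least `min_gap_h` hours; denser tables are
#' `"full"`; tables with fewer than two samples per condition cannot be
#' classified (`"ambiguous"`).
#'
#' @param df Data.frame with columns `condition, time_h, glycerol_gL,
#'   cdw_gL, pH` and optionally `od600`.
#' @param schedule `"auto"` (classify), `"full"` or `"sparse"`.
#' @param min_gap_h Minimum gap defining the sparse schedule, hours.
#' @return The data.frame with class `offline_table` and attribute
#'   `schedule`.
#' @export
offline_table <- function(df, schedule = c("auto", "full", "sparse"),
                          min_gap_h = 5) {
  schedule <- match.arg(schedule)
  need <- c("condition", "time_h", "glycerol_gL", "cdw_gL", "pH")
  if (!all(need %in% names(df)))
    stop("offline table must have columns: ", paste(need, collapse = ", "))
  if (any(df$glycerol_gL < 0) || any(df$cdw_gL < 0))
    stop("negative concentrations in offline table")
  if (any(df$pH <= 0 | df$pH >= 14))
    stop("pH values must lie in (0, 14)")
  df <- df[order(df$condition, df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  for (cond in unique(df$condition)) {
    tt <- df$time_h[df$condition == cond]
    if (anyDuplicated(tt) > 0L)
      stop("duplicate sampling times for condition ", cond)
  }
  if (schedule == "auto") schedule <- classify_schedule(df, min_gap_h)
  structure(df, class = c("offline_table", "data.frame"), schedule = schedule)
}

classify_schedule <- function(df, min_gap_h = 5) {
  per_cond <- split(df$time_h, df$condition)
  if (any(vapply(per_cond, length, integer(1)) < 2L)) return("ambiguous")
  sparse <- vapply(per_cond, function(tt) {
    n <- length(tt)
    n >= 6L && n <= 8L && all(diff(sort(tt)) >= min_gap_h)
  }, logical(1))
  if (all(sparse)) "sparse" else "full"
}

#' Read an offline sample table from CSV
#' @param path CSV with columns `condition, time_h, glycerol_gL, cdw_gL,
#'   pH` and optionally `od600`.
#' @inheritParams offline_table
#' @return An `offline_table`.
#' @export
read_offline_table <- function(path, schedule = "auto", min_gap_h = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(data.table::fread(path))
  offline_table(df, schedule = schedule, min_gap_h = min_gap_h)
}

#' Write an offline sample table to CSV
#' @param table An `offline_table` or plain data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offline_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}
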