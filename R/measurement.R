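#' Single 2D fluorescence measurement
#'
#' One excitation x emission intensity matrix recorded for one well at one
#' time point. A logical validity mask of the same shape tracks pixels that
#' later preprocessing steps (emission windowing, scattered-light exclusion)
#' remove; masked pixels carry `NA` intensity.
#'
#' @param well_id Well label, e.g. `"A1"`.
#' @param time Measurement time in hours.
#' @param intensities Numeric matrix, rows = excitation, cols = emission.
#' @param grid The shared `eem_grid`.
#' @param valid Logical matrix of the same shape; `TRUE` = usable pixel.
#'   Defaults to all valid.
#' @param check_nonnegative Raw (un-referenced) intensities must be >= 0;
#'   set `FALSE` for referenced (I - I0) spectra, which may be negative.
#' @return Object of class `eem_measurement`.
#' @export
eem_measurement <- function(well_id, time, intensities, grid,
                            valid = NULL, check_nonnegative = TRUE) {
  stopifnot(inherits(grid, "eem_grid"), is.matrix(intensities))
  d <- dim_eem(grid)
  if (!all(dim(intensities) == d))
    stop(sprintf("intensity matrix is %dx%d but grid is %dx%d",
                 nrow(intensities), ncol(intensities), d[1], d[2]))
  if (is.null(valid)) {
    valid <- matrix(TRUE, d[1], d[2])
  } else {
    stopifnot(is.logical(valid), all(dim(valid) == d))
  }
  if (check_nonnegative && any(intensities[valid] < 0, na.rm = TRUE))
    stop("raw intensities must be non-negative")
  structure(list(well_id = as.character(well_id), time = as.numeric(time),
                 intensities = intensities, grid = grid, valid = valid),
            class = "eem_measurement")
}

#' @export
print.eem_measurement <- function(x, ...) {
  cat(sprintf("EEM measurement: well %s at %.2f h, %d x %d pixels (%d valid)\n",
              x$well_id, x$time, nrow(x$intensities), ncol(x$intensities),
              sum(x$valid)))
  invisible(x)
}

#' Time series of 2D spectra for one well
#'
#' @param well_id Well label.
#' @param condition_id Culture-condition label the well belongs to.
#' @param measurements List of `eem_measurement`, strictly increasing times,
#'   all sharing one grid.
#' @param cadence Nominal measurement interval, hours (default 0.5).
#' @return Object of class `spectrum_series`.
#' @export
spectrum_series <- function(well_id, condition_id, measurements, cadence = 0.5) {
  stopifnot(length(measurements) >= 1L)
  lapply(measurements, function(m) stopifnot(inherits(m, "eem_measurement")))
  times <- vapply(measurements, `[[`, numeric(1), "time")
  if (is.unsorted(times, strictly = TRUE))
    stop("measurement times must be strictly increasing for well ", well_id)
  g <- measurements[[1]]$grid
  for (m in measurements[-1])
    if (!grids_identical(g, m$grid))
      stop("all measurements in a series must share one grid (well ", well_id, ")")
  structure(list(well_id = as.character(well_id),
                 condition_id = as.character(condition_id),
                 measurements = measurements, cadence = cadence),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  times <- series_times(x)
  cat(sprintf("Spectrum series: well %s (condition %s), %d spectra, %.2f-%.2f h\n",
              x$well_id, x$condition_id, length(x$measurements),
              min(times), max(times)))
  invisible(x)
}

#' Measurement times of a series
#' @param series A `spectrum_series`.
#' @return Numeric vector of hours.
#' @export
series_times <- function(series) {
  vapply(series$measurements, `[[`, numeric(1), "time")
}

#' Extract a single-pixel intensity trace
#'
#' Reads one detector pixel over time, snapping the requested wavelength
#' pair to the nearest grid node (no interpolation). The conventional
#' biomass proxy is the scattered-light pixel at ex = em = 600 nm and the
#' GFP readout is ex 420 / em 530 nm.
#'
#' @param series A `spectrum_series`.
#' @param ex_nm,em_nm Requested excitation / emission wavelength, nm. Must
#'   lie within the grid range on each axis.
#' @return A data.frame with columns `time` and `intensity` (NA where the
#'   pixel is masked); attributes `ex_nm` and `em_nm` report the grid node
#'   actually used.
#' @export
extract_channel <- function(series, ex_nm, em_nm) {
  stopifnot(inherits(series, "spectrum_series"))
  g <- series$measurements[[1]]$grid
  if (ex_nm < min(g$excitation) || ex_nm > max(g$excitation))
    stop("requested excitation ", ex_nm, " nm outside grid range")
  if (em_nm < min(g$emission) || em_nm > max(g$emission))
    stop("requested emission ", em_nm, " nm outside grid range")
  i <- which.min(abs(g$excitation - ex_nm))
  j <- which.min(abs(g$emission - em_nm))
  out <- data.frame(
    time = series_times(series),
    intensity = vapply(series$measurements, function(m) {
      if (m$valid[i, j]) m$intensities[i, j] else NA_real_
    }, numeric(1))
  )
  attr(out, "ex_nm") <- g$excitation[i]
  attr(out, "em_nm") <- g$emission[j]
  out
}
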