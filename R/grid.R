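#' Excitation-emission wavelength grid
#'
#' Defines the rectangular wavelength grid on which every 2D fluorescence
#' spectrum of an experiment is recorded: an excitation axis with uniform
#' spacing and an emission axis with (near-)uniform spacing.
#'
#' @param excitation Numeric vector of excitation wavelengths in nm,
#'   strictly increasing with uniform spacing.
#' @param emission Numeric vector of emission wavelengths in nm, strictly
#'   increasing; spacing must be uniform within `tol`.
#' @param tol Allowed deviation of emission spacing from uniformity, nm.
#' @return An object of class `eem_grid` with elements `excitation` and
#'   `emission`.
#' @examples
#' g <- eem_grid(seq(280, 700, by = 10), seq(278, 720, by = 0.45))
#' dim_eem(g)
#' @export
eem_grid <- function(excitation, emission, tol = 1e-6) {
  excitation <- as.numeric(excitation)
  emission <- as.numeric(emission)
  if (length(excitation) < 1L || length(emission) < 1L)
    stop("grid axes must be non-empty")
  if (is.unsorted(excitation, strictly = TRUE))
    stop("excitation wavelengths must be strictly increasing")
  if (is.unsorted(emission, strictly = TRUE))
    stop("emission wavelengths must be strictly increasing")
  if (length(excitation) > 1L) {
    dex <- diff(excitation)
    if (max(dex) - min(dex) > tol)
      stop("excitation spacing must be uniform")
  }
  if (length(emission) > 1L) {
    dem <- diff(emission)
    if (max(dem) - min(dem) > tol)
      stop("emission spacing not uniform within tolerance (", tol, " nm)")
  }
  structure(list(excitation = excitation, emission = emission),
            class = "eem_grid")
}

#' Default instrument grid presets
#'
#' Two emission-axis conventions are in circulation for the monitored
#' instrument: 278--720 nm at 0.45 nm steps (`"caption"`, the default) and
#' 275--725 nm at 0.44 nm steps (`"methods"`). Excitation is always
#' 280--700 nm in 10 nm increments.
#'
#' @param preset `"caption"` or `"methods"`.
#' @return An `eem_grid`.
#' @export
default_grid <- function(preset = c("caption", "methods")) {
  preset <- match.arg(preset)
  ex <- seq(280, 700, by = 10)
  em <- switch(preset,
    caption = seq(278, 720, by = 0.45),
    methods = seq(275, 725, by = 0.44)
  )
  eem_grid(ex, em)
}

#' @export
print.eem_grid <- function(x, ...) {
  cat(sprintf(
    "EEM grid: excitation %g-%g nm (n=%d, step %g), emission %g-%g nm (n=%d, step %g)\n",
    min(x$excitation), max(x$excitation), length(x$excitation),
    if (length(x$excitation) > 1) x$excitation[2] - x$excitation[1] else NA,
    min(x$emission), max(x$emission), length(x$emission),
    if (length(x$emission) > 1) x$emission[2] - x$emission[1] else NA))
  invisible(x)
}

#' Grid dimensions
#' @param grid An `eem_grid`.
#' @return Integer vector `c(n_excitation, n_emission)`.
#' @export
dim_eem <- function(grid) {
  stopifnot(inherits(grid, "eem_grid"))
  c(length(grid$excitation), length(grid$emission))
}

grids_identical <- function(a, b, tol = 1e-9) {
  length(a$excitation) == length(b$excitation) &&
    length(a$emission) == length(b$emission) &&
    max(abs(a$excitation - b$excitation)) <= tol &&
    max(abs(a$emission - b$emission)) <= tol
}
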