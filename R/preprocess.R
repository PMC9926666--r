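# Spectral preprocessing chain. Fixed step order in preprocess_series():
# emission window -> moving-average smoothing -> downsampling ->
# optional scattered-light masking -> referencing to the first spectrum.
# Every step is pure and per-measurement except referencing (per-well).

#' Preprocessing configuration
#'
#' @param em_window_rel Emission window relative to the excitation
#'   wavelength, nm, `c(low, high)`; pixels outside are masked. `NULL`
#'   disables the step.
#' @param smooth_window_px Moving-average window in pixels (odd, >= 1);
#'   1 disables smoothing.
#' @param target_em_step Target emission resolution after downsampling,
#'   nm; `NULL` disables the step.
#' @param scatter_band_rel Scattered-light band relative to excitation,
#'   nm; masked only when `include_scatter = FALSE`.
#' @param include_scatter Keep the scattered-light band (`TRUE`) or mask
#'   it to obtain fluorescence-only spectra (`FALSE`).
#' @param reference_to_t0 Subtract each well's first spectrum (I - I0).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(em_window_rel = c(-10, 270),
                              smooth_window_px = 25,
                              target_em_step = 2,
                              scatter_band_rel = c(-10, 13),
                              include_scatter = TRUE,
                              reference_to_t0 = TRUE) {
  if (!is.null(em_window_rel)) {
    stopifnot(length(em_window_rel) == 2L, em_window_rel[1] < em_window_rel[2])
  }
  stopifnot(smooth_window_px >= 1, smooth_window_px %% 2 == 1)
  if (!is.null(target_em_step)) stopifnot(target_em_step > 0)
  stopifnot(length(scatter_band_rel) == 2L,
            scatter_band_rel[1] < scatter_band_rel[2])
  structure(list(em_window_rel = em_window_rel,
                 smooth_window_px = as.integer(smooth_window_px),
                 target_em_step = target_em_step,
                 scatter_band_rel = scatter_band_rel,
                 include_scatter = isTRUE(include_scatter),
                 reference_to_t0 = isTRUE(reference_to_t0)),
            class = "preprocess_config")
}

# matrix of (em - ex) offsets, rows = excitation, cols = emission
offset_matrix <- function(grid) {
  outer(grid$excitation, grid$emission, function(ex, em) em - ex)
}

mask_pixels <- function(m, drop) {
  m$valid <- m$valid & !drop
  m$intensities[!m$valid] <- NA_real_
  m
}

#' Restrict the emission window relative to excitation
#'
#' Keeps, for each excitation row, only emission pixels whose offset
#' (em - ex) lies inside the window (default -10 to +270 nm); everything
#' else is masked. The grid is unchanged.
#'
#' @param m An `eem_measurement`.
#' @param window_rel `c(low, high)` in nm relative to excitation,
#'   inclusive on both ends.
#' @return The masked `eem_measurement`.
#' @export
restrict_emission_window <- function(m, window_rel = c(-10, 270)) {
  stopifnot(inherits(m, "eem_measurement"), window_rel[1] < window_rel[2])
  off <- offset_matrix(m$grid)
  out <- mask_pixels(m, off < window_rel[1] | off > window_rel[2])
  if (any(rowSums(out$valid) == 0L & rowSums(m$valid) > 0L))
    message("emission window masked entire excitation row(s)")
  out
}

#' Mask the scattered-light band
#'
#' Masks pixels with (em - ex) inside the band (default -10 to +13 nm,
#' both ends inclusive), removing the elastic scattering diagonal so that
#' models see fluorescence only.
#'
#' @param m An `eem_measurement`.
#' @param band_rel `c(low, high)` in nm relative to excitation.
#' @return The masked `eem_measurement`.
#' @export
mask_scatter <- function(m, band_rel = c(-10, 13)) {
  stopifnot(inherits(m, "eem_measurement"), band_rel[1] < band_rel[2])
  off <- offset_matrix(m$grid)
  mask_pixels(m, off >= band_rel[1] & off <= band_rel[2])
}

#' Moving-average smoothing along the emission axis
#'
#' Unweighted moving average over the valid pixels of each excitation row.
#' At the row edges the window truncates to the available pixels; masked
#' pixels neither contribute nor get filled.
#'
#' @param m An `eem_measurement`.
#' @param window_px Odd window size in pixels.
#' @return The smoothed `eem_measurement`.
#' @export
smooth_emission <- function(m, window_px = 25) {
  stopifnot(inherits(m, "eem_measurement"),
            window_px >= 1, window_px %% 2 == 1)
  if (window_px == 1) return(m)
  n <- ncol(m$intensities)
  if (window_px > n)
    message("smoothing window (", window_px,
            " px) exceeds row length (", n, "); rows collapse to their mean")
  h <- (window_px - 1L) %/% 2L
  vals <- m$intensities
  vals[!m$valid] <- 0
  cnt <- matrix(as.numeric(m$valid), nrow(vals), n)
  cs_v <- t(apply(vals, 1L, cumsum))
  cs_c <- t(apply(cnt, 1L, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  wsum <- cs_v[, hi, drop = FALSE] -
    cbind(0, cs_v)[, lo, drop = FALSE]
  wcnt <- cs_c[, hi, drop = FALSE] -
    cbind(0, cs_c)[, lo, drop = FALSE]
  sm <- wsum / wcnt
  sm[!m$valid] <- NA_real_
  m$intensities <- sm
  m
}

#' Downsample the emission axis by bin averaging
#'
#' Rebuilds the emission axis at `target_step_nm` starting from the first
#' emission wavelength; each output pixel is the mean of the valid native
#' pixels whose wavelength falls in `[center - step/2, center + step/2)`.
#' An output pixel is masked iff all its contributors are masked.
#'
#' @param m An `eem_measurement`.
#' @param target_step_nm Target step, nm; must be >= the native step.
#' @return An `eem_measurement` on the coarser grid.
#' @export
downsample_emission <- function(m, target_step_nm = 2) {
  stopifnot(inherits(m, "eem_measurement"))
  em <- m$grid$emission
  native <- if (length(em) > 1) em[2] - em[1] else target_step_nm
  if (target_step_nm < native - 1e-9)
    stop("target step (", target_step_nm,
         " nm) smaller than native step (", native, " nm)")
  K <- floor((max(em) - min(em)) / target_step_nm)
  centers <- min(em) + target_step_nm * (0:K)
  bin <- floor((em - min(em)) / target_step_nm + 0.5)
  keep <- bin >= 0 & bin <= K
  B <- matrix(0, length(em), K + 1L)
  B[cbind(which(keep), bin[keep] + 1L)] <- 1
  vals <- m$intensities
  vals[!m$valid] <- 0
  sums <- vals %*% B
  cnts <- (m$valid * 1) %*% B
  newvals <- sums / cnts
  newvalid <- cnts > 0
  newvals[!newvalid] <- NA_real_
  grid2 <- eem_grid(m$grid$excitation, centers)
  eem_measurement(m$well_id, m$time, newvals, grid2, valid = newvalid,
                  check_nonnegative = FALSE)
}

#' Reference a series to its first spectrum (I - I0)
#'
#' Replaces every measurement of a well by the pixel-wise difference to the
#' well's first spectrum, so that models see cultivation-induced spectral
#' change rather than the medium background. The first spectrum of the
#' output is identically zero; later differences may be negative. Applying
#' the step twice is not a no-op for the later spectra's interpretation and
#' is not prevented.
#'
#' @param series A `spectrum_series` whose measurements share one mask.
#' @return The referenced `spectrum_series`.
#' @export
reference_to_initial <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  v0 <- series$measurements[[1]]$valid
  for (m in series$measurements)
    if (!identical(dim(m$valid), dim(v0)) || !all(m$valid == v0))
      stop("inconsistent masks across time in well ", series$well_id,
           "; referencing requires a shared mask")
  i0 <- series$measurements[[1]]$intensities
  series$measurements <- lapply(series$measurements, function(m) {
    m$intensities <- m$intensities - i0
    m$intensities[!m$valid] <- NA_real_
    m
  })
  series
}

#' Unfold a measurement into a feature vector
#'
#' Flattens the valid pixels in deterministic excitation-major,
#' emission-minor order. Identical grids and masks yield identical feature
#' indices across wells and times, which is what makes unfolded spectra
#' stackable into a regression matrix.
#'
#' @param m An `eem_measurement`.
#' @return A list with `values` (numeric vector) and `index` (data.frame
#'   `feature_id, ex_nm, em_nm`).
#' @export
unfold_to_features <- function(m) {
  stopifnot(inherits(m, "eem_measurement"))
  tv <- t(m$valid)            # em x ex; column-major walk = ex-major order
  keep <- which(tv)
  if (length(keep) == 0L) stop("no valid pixels to unfold")
  em_i <- ((keep - 1L) %% nrow(tv)) + 1L
  ex_j <- ((keep - 1L) %/% nrow(tv)) + 1L
  list(values = t(m$intensities)[keep],
       index = data.frame(feature_id = seq_along(keep),
                          ex_nm = m$grid$excitation[ex_j],
                          em_nm = m$grid$emission[em_i]))
}

#' Refold a feature vector back onto its grid
#'
#' Inverse of [unfold_to_features()] on the valid pixels; everything not in
#' the index stays `NA`/masked.
#'
#' @param values Numeric feature vector.
#' @param index Feature index as returned by [unfold_to_features()].
#' @param grid The `eem_grid` to refold onto.
#' @return A matrix (excitation x emission).
#' @export
refold_features <- function(values, index, grid) {
  stopifnot(length(values) == nrow(index))
  mat <- matrix(NA_real_, length(grid$excitation), length(grid$emission))
  i <- match(index$ex_nm, grid$excitation)
  j <- match(index$em_nm, grid$emission)
  if (anyNA(i) || anyNA(j)) stop("feature index does not match grid")
  mat[cbind(i, j)] <- values
  mat
}

#' Run the full preprocessing chain on a series
#'
#' Applies, in fixed order: emission windowing, moving-average smoothing,
#' emission downsampling, optional scattered-light masking (when
#' `include_scatter = FALSE`), and referencing to the first spectrum.
#'
#' @param series A `spectrum_series` of raw measurements.
#' @param cfg A [preprocess_config()].
#' @return The preprocessed `spectrum_series`.
#' @export
preprocess_series <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "spectrum_series"),
            inherits(cfg, "preprocess_config"))
  step <- function(f) {
    series$measurements <<- lapply(series$measurements, f)
  }
  if (!is.null(cfg$em_window_rel))
    step(function(m) restrict_emission_window(m, cfg$em_window_rel))
  if (cfg$smooth_window_px > 1L)
    step(function(m) smooth_emission(m, cfg$smooth_window_px))
  if (!is.null(cfg$target_em_step))
    step(function(m) downsample_emission(m, cfg$target_em_step))
  if (!cfg$include_scatter)
    step(function(m) mask_scatter(m, cfg$scatter_band_rel))
  if (cfg$reference_to_t0)
    series <- reference_to_initial(series)
  series
}

#' Preprocess every series of a plate experiment
#'
#' @param experiment A `plate_experiment`.
#' @param cfg A [preprocess_config()].
#' @return A named list of preprocessed `spectrum_series`.
#' @export
preprocess_experiment <- function(experiment, cfg = preprocess_config()) {
  stopifnot(inherits(experiment, "plate_experiment"))
  lapply(experiment$spectra, preprocess_series, cfg = cfg)
}
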