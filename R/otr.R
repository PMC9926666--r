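# Oxygen-transfer-rate monitoring: Stern-Volmer optode inversion and a
# stop-flow headspace balance. During a measuring (stop-flow) phase the
# headspace is sealed, so the O2 partial-pressure decline rate times the
# molar gas content per liquid volume gives the OTR.

O2_FRACTION_AIR <- 0.2095   # bar O2 per bar air at 1 atm
R_GAS <- 0.0831446          # L bar / (mol K)

#' Headspace pO2 trace
#'
#' @param well_id Well label.
#' @param times Hours, strictly increasing.
#' @param po2 Oxygen partial pressure; unit per `unit`.
#' @param phase Character/factor per point: `"measuring"` (stop-flow) or
#'   `"flushing"`. Default: all measuring.
#' @param unit `"percent_air_sat"` (converted internally assuming 0.2095
#'   bar O2 at 1 atm) or `"bar"`.
#' @return Object of class `po2_trace` (pO2 stored in bar).
#' @export
po2_trace <- function(well_id, times, po2,
                      phase = rep("measuring", length(times)),
                      unit = c("percent_air_sat", "bar")) {
  unit <- match.arg(unit)
  stopifnot(length(times) == length(po2), length(phase) == length(po2))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(po2 < 0)) stop("pO2 must be non-negative")
  if (unit == "percent_air_sat") po2 <- po2 / 100 * O2_FRACTION_AIR
  structure(list(well_id = as.character(well_id), times = as.numeric(times),
                 po2 = as.numeric(po2), phase = as.character(phase)),
            class = "po2_trace")
}

#' Invert optode quenching to oxygen partial pressure
#'
#' Stern-Volmer quenching, `I0/I = 1 + Ksv * pO2`, inverted to
#' `pO2 = (I0/I - 1) / Ksv`. Measurement noise can push `I` slightly above
#' `I0`; the resulting small negative pO2 is clamped to 0 with a warning.
#'
#' @param i0 Unquenched optode intensity (pO2 = 0), > 0.
#' @param i Measured intensity, > 0.
#' @param ksv Stern-Volmer constant, 1 / pressure-unit.
#' @return pO2 in the reciprocal unit of `ksv`.
#' @export
stern_volmer_po2 <- function(i0, i, ksv) {
  stopifnot(all(i0 > 0), all(ksv > 0))
  if (any(i <= 0)) stop("optode intensity must be positive")
  p <- (i0 / i - 1) / ksv
  if (any(p < 0)) {
    warning("intensity above I0 (noise); pO2 clamped at 0")
    p <- pmax(p, 0)
  }
  p
}

#' Oxygen transfer rate from a stop-flow headspace trace
#'
#' Within each contiguous measuring phase the pO2 decline slope is
#' estimated by ordinary least squares over `window` points centered on
#' the phase midpoint, and converted through the ideal-gas headspace
#' balance `OTR = -(dpO2/dt) * Vg / (Vl * R * T)` to mmol O2 / L liquid /
#' h. One OTR value is reported per phase, at the phase midpoint time.
#' Phases with fewer than `window` points are skipped with a warning.
#'
#' @param trace A [po2_trace()].
#' @param vg Headspace gas volume, L.
#' @param vl Liquid volume, L.
#' @param temperature K.
#' @param window Number of points for the slope fit.
#' @return Data.frame of class `otr_trace`: `well, time, otr_mmol_L_h`.
#' @export
otr_from_po2 <- function(trace, vg, vl, temperature = 303.15, window = 5) {
  stopifnot(inherits(trace, "po2_trace"), vg > 0, vl > 0, window >= 2)
  meas <- trace$phase == "measuring"
  # contiguous runs of measuring points
  runs <- rle(meas)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  out <- list()
  skipped <- 0L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    ii <- idx_start[k]:idx_end[k]
    if (length(ii) < window) { skipped <- skipped + 1L; next }
    mid <- ii[ceiling(length(ii) / 2)]
    half <- (window - 1) %/% 2
    lo <- max(ii[1], mid - half)
    hi <- min(ii[length(ii)], lo + window - 1L)
    lo <- max(ii[1], hi - window + 1L)
    sel <- lo:hi
    tt <- trace$times[sel]; pp <- trace$po2[sel]
    slope <- sum((tt - mean(tt)) * (pp - mean(pp))) / sum((tt - mean(tt))^2)
    out[[length(out) + 1L]] <- data.frame(
      well = trace$well_id,
      time = trace$times[mid],
      otr_mmol_L_h = -slope * vg / (vl * R_GAS * temperature) * 1000)
  }
  if (skipped > 0L)
    warning(skipped, " measuring phase(s) shorter than the window were skipped")
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(well = character(), time = numeric(), otr_mmol_L_h = numeric())
  class(res) <- c("otr_trace", "data.frame")
  res
}
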