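#' Culture condition table helper
#'
#' Builds the per-condition metadata table of a plate experiment. Each
#' condition holds a fraction of the full supplementation of the limited
#' secondary substrate, an inoculation density, its replicate wells and a
#' role in the chemometric workflow.
#'
#' @param condition_id Character vector of condition labels.
#' @param substrate_fraction Fraction of full supplementation in `[0, 1]`.
#' @param substrate_conc Actual concentration, mg/L (printed precision).
#' @param cdw_t0 Inoculation cell dry weight, g/L (0 for blanks).
#' @param role One of `"calibration"`, `"prediction"`, `"blank"` per row.
#' @return A data.frame of class `culture_conditions`.
#' @export
culture_conditions <- function(condition_id, substrate_fraction,
                               substrate_conc, cdw_t0, role) {
  role <- match.arg(role, c("calibration", "prediction", "blank"),
                    several.ok = TRUE)
  stopifnot(all(substrate_fraction >= 0 & substrate_fraction <= 1),
            all(cdw_t0 >= 0))
  if (any(role == "blank" & cdw_t0 != 0))
    stop("blank conditions must have cdw_t0 = 0")
  df <- data.frame(condition_id = as.character(condition_id),
                   substrate_fraction = substrate_fraction,
                   substrate_conc = substrate_conc,
                   cdw_t0 = cdw_t0, role = role,
                   stringsAsFactors = FALSE)
  class(df) <- c("culture_conditions", "data.frame")
  df
}

#' Plate experiment container
#'
#' Bundles everything recorded for one microtiter-plate cultivation under
#' one secondary-substrate limitation: the condition table, the well ->
#' condition map, all spectral time series, the (full-schedule) offline
#' table, optional per-well headspace pO2 traces and the analysis time
#' cutoff.
#'
#' @param experiment_id Label.
#' @param limited_substrate `"Mg"`, `"K"`, `"PO4"` or `"none"`.
#' @param conditions A `culture_conditions` table.
#' @param well_map Data.frame `well_id, condition_id`.
#' @param spectra List of `spectrum_series`.
#' @param offline An `offline_table` (full schedule).
#' @param po2 Optional named list of per-well pO2 traces (see
#'   [po2_trace()]).
#' @param t_max_model Analysis cutoff in hours; `Inf` keeps everything.
#'   Must not exceed the last spectral time.
#' @param full_conc Full-supplementation concentration of the limited
#'   substrate, mg/L.
#' @return Object of class `plate_experiment`.
#' @export
plate_experiment <- function(experiment_id, limited_substrate, conditions,
                             well_map, spectra, offline, po2 = NULL,
                             t_max_model = Inf, full_conc = NA_real_) {
  limited_substrate <- match.arg(limited_substrate,
                                 c("Mg", "K", "PO4", "none"))
  stopifnot(inherits(conditions, "culture_conditions"))
  conds <- conditions$condition_id
  for (s in spectra) {
    if (!is.na(s$condition_id) && !(s$condition_id %in% conds))
      stop("spectrum series for well ", s$well_id,
           " references unknown condition ", s$condition_id)
  }
  if (length(spectra) > 0L && is.finite(t_max_model)) {
    t_last <- max(vapply(spectra, function(s) max(series_times(s)), numeric(1)))
    if (t_max_model > t_last + 1e-9)
      stop("t_max_model exceeds the last spectral time (", t_last, " h)")
  }
  structure(list(experiment_id = experiment_id,
                 limited_substrate = limited_substrate,
                 conditions = conditions, well_map = well_map,
                 spectra = spectra, offline = offline, po2 = po2,
                 t_max_model = t_max_model, full_conc = full_conc),
            class = "plate_experiment")
}

#' @export
print.plate_experiment <- function(x, ...) {
  cat(sprintf(
    "Plate experiment '%s' (%s limitation): %d conditions, %d wells with spectra, t_max_model = %s h\n",
    x$experiment_id, x$limited_substrate, nrow(x$conditions),
    length(x$spectra),
    if (is.finite(x$t_max_model)) format(x$t_max_model) else "none"))
  print(as.data.frame(x$conditions))
  invisible(x)
}
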