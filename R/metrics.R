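# RMSE metrics, the latent-variable scan over the dual-RMSE validation
# scheme, LV selection, and trajectory prediction.

#' Root-mean-square error
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty vectors")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

#' Relative RMSE in percent of the measured range
#'
#' Expresses an absolute RMSE as a percentage of the range (max - min) of
#' the experiment's measured offline values for the parameter. Note that
#' the reference range is a property of the experiment's measured values,
#' not of any single dataset; supply the values the error should be judged
#' against.
#'
#' @param rmse_value Absolute RMSE, parameter units.
#' @param y_reference Measured offline values defining the range.
#' @return `100 * rmse_value / diff(range(y_reference))`.
#' @export
relative_rmse <- function(rmse_value, y_reference) {
  rng <- max(y_reference) - min(y_reference)
  if (rng <= 0) stop("reference range is zero")
  100 * rmse_value / rng
}

#' Scan RMSE over the number of latent variables
#'
#' For each latent-variable count 1..`L_max`, fits SIMPLS on the sparse
#' calibration dataset and evaluates four errors: `rmse_cal_sparse`
#' (against the sparse-interpolated calibration responses),
#' `rmse_cal_full` (same spectra, densely interpolated responses),
#' `rmse_pred_full` (held-out conditions), and `rmse_pred_full_m100`
#' (held-out conditions excluding the fully supplemented one, which lies
#' outside the calibration span). SIMPLS components are nested, so a
#' single fit at `L_max` yields every sub-model exactly.
#'
#' @param cal_sparse,cal_full,pred_full `regression_dataset`s sharing one
#'   feature index (see [split_calibration_prediction()]).
#' @param full_condition_id Condition id(s) of the fully supplemented
#'   culture(s) excluded in the -100% variant.
#' @param L_max Largest latent-variable count to scan (>= 2). Capped with
#'   a warning if it exceeds what the calibration data supports.
#' @return Object of class `lv_scan`: a data.frame with columns `n_lv`,
#'   `rmse_cal_sparse`, `rmse_cal_full`, `rmse_pred_full`,
#'   `rmse_pred_full_m100`.
#' @export
lv_scan <- function(cal_sparse, cal_full, pred_full, full_condition_id,
                    L_max = 10) {
  stopifnot(L_max >= 2)
  if (ncol(cal_sparse$X) != ncol(pred_full$X) ||
      ncol(cal_sparse$X) != ncol(cal_full$X))
    stop("datasets do not share one feature index")
  L_cap <- min(L_max, nrow(cal_sparse$X) - 1L)
  fit <- NULL
  for (L in L_cap:1) {
    fit <- tryCatch(simpls(cal_sparse$X, cal_sparse$y, ncomp = L),
                    error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("could not fit a single latent variable")
  if (fit$ncomp < L_max)
    warning("LV scan capped at ", fit$ncomp, " of the requested ",
            L_max, " latent variables")
  m100 <- !(pred_full$meta$condition %in% full_condition_id)
  rows <- lapply(seq_len(fit$ncomp), function(a) {
    yhat_cal <- predict(fit, cal_sparse$X, ncomp = a)
    yhat_pred <- predict(fit, pred_full$X, ncomp = a)
    data.frame(
      n_lv = a,
      rmse_cal_sparse = rmse(cal_sparse$y, yhat_cal),
      rmse_cal_full = rmse(cal_full$y, yhat_cal),
      rmse_pred_full = rmse(pred_full$y, yhat_pred),
      rmse_pred_full_m100 = if (any(m100))
        rmse(pred_full$y[m100], yhat_pred[m100]) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lv_scan", "data.frame")
  out
}

#' Select the number of latent variables from an LV scan
#'
#' Primary (divergence) rule: the smallest `n_lv` at which the calibration
#' error against the densely sampled reference starts to rise
#' (`rmse_cal_full(n+1) > rmse_cal_full(n)`) while the error against the
#' sparse calibration reference still falls
#' (`rmse_cal_sparse(n+1) < rmse_cal_sparse(n)`) — the point where the
#' model begins fitting the sparse interpolation instead of the underlying
#' spectral dynamics. If no such index exists, the fallback picks the
#' minimum of `rmse_pred_full_m100`, ties broken toward fewer latent
#' variables.
#'
#' @param scan An `lv_scan`.
#' @return List with `n_lv` and `rule` (`"divergence"` or
#'   `"min_pred_m100"`).
#' @export
select_n_lv <- function(scan) {
  stopifnot(inherits(scan, "lv_scan"), nrow(scan) >= 2L)
  cf <- scan$rmse_cal_full
  cs <- scan$rmse_cal_sparse
  for (i in seq_len(nrow(scan) - 1L)) {
    if (cf[i + 1L] > cf[i] && cs[i + 1L] < cs[i])
      return(list(n_lv = scan$n_lv[i], rule = "divergence"))
  }
  m <- scan$rmse_pred_full_m100
  if (all(is.na(m))) m <- scan$rmse_pred_full
  list(n_lv = scan$n_lv[which.min(m)], rule = "min_pred_m100")
}

#' Predict offline-parameter trajectories for every well
#'
#' Applies a fitted SIMPLS model to every preprocessed spectrum of every
#' non-blank well up to the analysis cutoff and returns the calculated
#' parameter progression in tidy form.
#'
#' @param model A `simpls` model.
#' @param spectra Named list of preprocessed `spectrum_series` (same
#'   preprocessing configuration as the training data).
#' @param experiment The `plate_experiment` (for roles and the cutoff).
#' @param parameter Parameter label recorded in the output.
#' @return Data.frame `well, condition, time, parameter, prediction`.
#' @export
predict_trajectories <- function(model, spectra, experiment, parameter) {
  stopifnot(inherits(model, "simpls"), inherits(experiment, "plate_experiment"))
  conds <- experiment$conditions
  blank_ids <- conds$condition_id[conds$role == "blank"]
  t_max <- experiment$t_max_model
  out <- list()
  for (s in spectra) {
    if (s$condition_id %in% blank_ids) next
    keep <- which(series_times(s) <= t_max + 1e-9)
    if (length(keep) == 0L) next
    Xw <- do.call(rbind, lapply(s$measurements[keep],
                                function(m) unfold_to_features(m)$values))
    out[[length(out) + 1L]] <- data.frame(
      well = s$well_id, condition = s$condition_id,
      time = series_times(s)[keep], parameter = parameter,
      prediction = pls_apply(model, Xw), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
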