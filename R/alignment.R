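# Temporal alignment of offline reference values to spectral timestamps
# and assembly of calibration / prediction regression datasets.

#' Linear interpolation of offline values
#'
#' Piecewise-linear interpolation of one condition's offline samples at the
#' spectral measurement times. No extrapolation: queries outside the
#' sampled range are an error.
#'
#' @param times Sample times, hours (>= 2, strictly increasing).
#' @param values Sample values.
#' @param query_times Times at which to evaluate.
#' @return Interpolated values, exact at the sample times.
#' @export
interpolate_offline <- function(times, values, query_times) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (is.unsorted(times, strictly = TRUE))
    stop("sample times must be strictly increasing")
  if (any(query_times < min(times) - 1e-9 | query_times > max(times) + 1e-9))
    stop("query times outside the sampled range [", min(times), ", ",
         max(times), "] h; extrapolation is not supported")
  stats::approx(times, values, xout = query_times, rule = 2)$y
}

#' Select a sparse sampling schedule from a full table
#'
#' Deterministic greedy thinning emulating a realistic manual sampling
#' plan: the first and last sample of each condition are always kept;
#' between them the earliest sample at least `min_gap_h` after the
#' previously chosen one is taken. If more than `n_max` samples result,
#' interior samples are dropped from the end (keeping first and last); if
#' fewer than `n_min` are achievable, selection fails.
#'
#' @param table An `offline_table` (full schedule).
#' @param min_gap_h Minimum gap between consecutive samples, hours.
#' @param n_min,n_max Acceptable number of samples per condition.
#' @return An `offline_table` with schedule `"sparse"`.
#' @export
select_sparse_schedule <- function(table, min_gap_h = 5, n_min = 6, n_max = 8) {
  stopifnot(inherits(table, "offline_table"))
  df <- as.data.frame(table)
  picked <- lapply(split(df, df$condition), function(dc) {
    dc <- dc[order(dc$time_h), , drop = FALSE]
    tt <- dc$time_h
    n <- length(tt)
    sel <- 1L
    repeat {
      nxt <- which(tt >= tt[sel[length(sel)]] + min_gap_h)
      if (length(nxt) == 0L) break
      sel <- c(sel, nxt[1L])
    }
    if (sel[length(sel)] != n) {
      if (tt[n] - tt[sel[length(sel)]] >= min_gap_h) {
        sel <- c(sel, n)
      } else {
        sel[length(sel)] <- n
      }
    }
    if (length(sel) > n_max) {
      interior <- sel[-c(1L, length(sel))]
      interior <- interior[seq_len(n_max - 2L)]
      sel <- c(sel[1L], interior, sel[length(sel)])
    }
    if (length(sel) < n_min)
      stop("condition ", dc$condition[1], ": only ", length(sel),
           " samples achievable with a ", min_gap_h,
           " h gap; at least ", n_min, " required")
    dc[sel, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  offline_table(out, schedule = "sparse", min_gap_h = min_gap_h)
}

param_column <- function(parameter) {
  switch(match.arg(parameter, c("glycerol", "cdw", "ph")),
         glycerol = "glycerol_gL", cdw = "cdw_gL", ph = "pH")
}

#' Assemble a regression dataset
#'
#' Stacks the unfolded preprocessed spectra of all replicate wells of the
#' listed conditions (times <= `t_max_model`) into a feature matrix `X` and
#' aligns the offline parameter by linear interpolation into the response
#' `y`. Replicate wells of one condition share the same interpolated
#' offline trace (offline sampling is per condition, not per well).
#' Spectral times before the first offline sample are dropped with a
#' warning; times after the last offline sample are likewise excluded.
#'
#' @param spectra Named list of preprocessed `spectrum_series`.
#' @param offline An `offline_table` covering the conditions.
#' @param conditions Character vector of condition ids to include.
#' @param parameter `"glycerol"`, `"cdw"` or `"ph"`.
#' @param t_max_model Analysis cutoff, hours (`Inf` keeps everything).
#' @return Object of class `regression_dataset`: list with `X` (rows =
#'   spectra), `y`, `meta` (well, condition, time), `parameter`,
#'   `schedule` (from the offline table), and `feature_index`.
#' @export
assemble_dataset <- function(spectra, offline, conditions, parameter,
                             t_max_model = Inf) {
  stopifnot(inherits(offline, "offline_table"))
  col <- param_column(parameter)
  off <- as.data.frame(offline)
  use <- Filter(function(s) s$condition_id %in% conditions, spectra)
  if (length(use) == 0L) stop("no spectra for the requested conditions")
  missing_off <- setdiff(conditions, unique(off$condition))
  if (length(missing_off) > 0L)
    stop("no offline data for condition(s): ",
         paste(missing_off, collapse = ", "))
  rows <- list(); ys <- list(); meta <- list()
  feature_index <- NULL
  dropped <- 0L
  for (s in use) {
    oc <- off[off$condition == s$condition_id, , drop = FALSE]
    t_lo <- min(oc$time_h); t_hi <- max(oc$time_h)
    for (m in s$measurements) {
      if (m$time > t_max_model + 1e-9) next
      if (m$time < t_lo - 1e-9 || m$time > min(t_hi, Inf) + 1e-9) {
        dropped <- dropped + 1L
        next
      }
      uf <- unfold_to_features(m)
      if (is.null(feature_index)) {
        feature_index <- uf$index
      } else if (nrow(uf$index) != nrow(feature_index) ||
                 any(uf$index$ex_nm != feature_index$ex_nm) ||
                 any(uf$index$em_nm != feature_index$em_nm)) {
        stop("spectra do not share one feature index; preprocess with one config")
      }
      k <- length(rows) + 1L
      rows[[k]] <- uf$values
      ys[[k]] <- interpolate_offline(oc$time_h, oc[[col]], m$time)
      meta[[k]] <- data.frame(well = s$well_id,
                              condition = s$condition_id,
                              time = m$time, stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0L)
    warning(dropped, " spectra outside the offline sampling range were dropped")
  if (length(rows) == 0L) stop("no usable rows after time filtering")
  meta <- do.call(rbind, meta)
  ord <- order(meta$condition, meta$well, meta$time)
  structure(list(X = do.call(rbind, rows)[ord, , drop = FALSE],
                 y = unlist(ys)[ord],
                 meta = meta[ord, , drop = FALSE],
                 parameter = match.arg(parameter, c("glycerol", "cdw", "ph")),
                 schedule = attr(offline, "schedule"),
                 feature_index = feature_index),
            class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf(
    "Regression dataset (%s, %s schedule): %d spectra x %d features, %d conditions\n",
    x$parameter, x$schedule, nrow(x$X), ncol(x$X),
    length(unique(x$meta$condition))))
  invisible(x)
}

#' Split an experiment into calibration and prediction datasets
#'
#' Builds, for one offline parameter, the three datasets of the dual-RMSE
#' validation scheme: calibration with sparse-schedule responses,
#' calibration with full-schedule responses (identical `X`, only `y`
#' differs), and prediction on the held-out conditions with full-schedule
#' responses. Blank conditions are excluded throughout.
#'
#' @param experiment A `plate_experiment`.
#' @param spectra Named list of preprocessed `spectrum_series` for the
#'   experiment's wells.
#' @param cal_condition_ids Exactly two condition ids (one high, one low
#'   supplementation).
#' @param parameter `"glycerol"`, `"cdw"` or `"ph"`.
#' @param sparse_min_gap_h Gap used to thin the full offline table.
#' @return List with elements `cal_sparse`, `cal_full`, `pred_full`
#'   (`regression_dataset`s).
#' @export
split_calibration_prediction <- function(experiment, spectra,
                                         cal_condition_ids, parameter,
                                         sparse_min_gap_h = 5) {
  stopifnot(inherits(experiment, "plate_experiment"))
  if (length(cal_condition_ids) != 2L ||
      length(unique(cal_condition_ids)) != 2L)
    stop("exactly two distinct calibration conditions are required")
  conds <- experiment$conditions
  non_blank <- conds$condition_id[conds$role != "blank"]
  if (!all(cal_condition_ids %in% non_blank))
    stop("calibration conditions must be non-blank conditions of the experiment")
  pred_ids <- setdiff(non_blank, cal_condition_ids)
  if (length(pred_ids) == 0L)
    stop("no conditions left for prediction after the calibration split")
  if (length(intersect(cal_condition_ids, pred_ids)) > 0L)
    stop("calibration and prediction conditions overlap")
  full <- experiment$offline
  sparse <- select_sparse_schedule(full, min_gap_h = sparse_min_gap_h)
  t_max <- experiment$t_max_model
  list(
    cal_sparse = assemble_dataset(spectra, sparse, cal_condition_ids,
                                  parameter, t_max),
    cal_full = assemble_dataset(spectra, full, cal_condition_ids,
                                parameter, t_max),
    pred_full = assemble_dataset(spectra, full, pred_ids, parameter, t_max)
  )
}
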