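# End-to-end orchestration: simulate (or accept) a plate experiment,
# preprocess, assemble datasets, scan latent variables, fit, predict and
# report. Numeric CSVs are the contract; figures are left to the user.

#' Analysis configuration for the full pipeline
#'
#' @param preset Synthetic experiment preset (`"Mg"`, `"K"`, `"PO4"`);
#'   ignored when `experiment` is supplied to [run_pipeline()].
#' @param seed Integer seed (mandatory in preset mode).
#' @param parameters Offline parameters to model.
#' @param L_max Largest latent-variable count scanned.
#' @param include_scatter Use scatter-included spectra for PLS modelling
#'   (`TRUE`) or fluorescence-only spectra (`FALSE`). PCA diagnostics are
#'   always computed for both.
#' @param preprocess A [preprocess_config()]; its `include_scatter` flag
#'   is overridden by the `include_scatter` argument.
#' @param cal_condition_ids Two calibration condition ids, or `NULL` to
#'   take the conditions with role `"calibration"`.
#' @param sim Optional [sim_config()] overriding the default preset
#'   configuration.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(preset = "Mg", seed = 1,
                            parameters = c("glycerol", "cdw", "ph"),
                            L_max = 10, include_scatter = TRUE,
                            preprocess = preprocess_config(),
                            cal_condition_ids = NULL, sim = NULL) {
  parameters <- match.arg(parameters, c("glycerol", "cdw", "ph"),
                          several.ok = TRUE)
  stopifnot(L_max >= 2)
  structure(list(preset = preset, seed = as.integer(seed),
                 parameters = parameters, L_max = L_max,
                 include_scatter = isTRUE(include_scatter),
                 preprocess = preprocess,
                 cal_condition_ids = cal_condition_ids, sim = sim),
            class = "analysis_config")
}

#' Run the full chemometric pipeline
#'
#' Stages: generate (or take) the plate experiment; preprocess spectra
#' both scatter-included and fluorescence-only; assemble the sparse/full
#' calibration and prediction datasets per parameter; scan latent
#' variables; select the count by the divergence rule (with the -100%
#' fallback); fit the final SIMPLS model; predict per-well trajectories;
#' compute absolute and relative RMSEs (full and -100% variants); run PCA
#' on both spectral variants. When `out_dir` is given, writes per-stage
#' CSVs and a JSON run manifest.
#'
#' @param cfg An [analysis_config()].
#' @param experiment Optional `plate_experiment`; when `NULL`, one is
#'   generated from `cfg$preset` and `cfg$seed`.
#' @param out_dir Optional output directory.
#' @return List of class `eemferm_run`: per-parameter results (`scan`,
#'   `selection`, `model`, `rmse`, `trajectories`), `pca` (both spectral
#'   variants), the `experiment`, and the `manifest`.
#' @export
run_pipeline <- function(cfg, experiment = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(experiment)) {
    sim <- if (!is.null(cfg$sim)) cfg$sim else
      sim_config(cfg$preset, seed = cfg$seed)
    experiment <- generate_experiment(sim)
  }
  pc_scatter <- cfg$preprocess; pc_scatter$include_scatter <- TRUE
  pc_fl <- cfg$preprocess; pc_fl$include_scatter <- FALSE
  prep_scatter <- preprocess_experiment(experiment, pc_scatter)
  prep_fl <- preprocess_experiment(experiment, pc_fl)
  prep_model <- if (cfg$include_scatter) prep_scatter else prep_fl
  cal_ids <- cfg$cal_condition_ids
  if (is.null(cal_ids))
    cal_ids <- experiment$conditions$condition_id[
      experiment$conditions$role == "calibration"]
  full_ids <- experiment$conditions$condition_id[
    experiment$conditions$substrate_fraction == 1 &
      experiment$conditions$role != "blank"]
  gap <- attr(experiment, "sparse_min_gap_h")
  if (is.null(gap)) gap <- 5
  results <- list()
  for (par in cfg$parameters) {
    ds <- split_calibration_prediction(experiment, prep_model, cal_ids, par,
                                       sparse_min_gap_h = gap)
    scan <- lv_scan(ds$cal_sparse, ds$cal_full, ds$pred_full, full_ids,
                    L_max = cfg$L_max)
    sel <- select_n_lv(scan)
    model <- simpls(ds$cal_sparse$X, ds$cal_sparse$y, ncomp = sel$n_lv)
    traj <- predict_trajectories(model, prep_model, experiment, par)
    col <- param_column(par)
    rng_ref <- as.data.frame(experiment$offline)[[col]]
    m100 <- !(ds$pred_full$meta$condition %in% full_ids)
    yhat_cal <- predict(model, ds$cal_full$X)
    yhat_pred <- predict(model, ds$pred_full$X)
    rmse_tbl <- data.frame(
      parameter = par,
      n_lv = sel$n_lv, rule = sel$rule,
      rmse_cal_sparse = rmse(ds$cal_sparse$y, yhat_cal),
      rmse_cal_full = rmse(ds$cal_full$y, yhat_cal),
      rmse_pred_full = rmse(ds$pred_full$y, yhat_pred),
      rmse_pred_full_m100 = if (any(m100))
        rmse(ds$pred_full$y[m100], yhat_pred[m100]) else NA_real_,
      stringsAsFactors = FALSE)
    rmse_tbl$rel_rmse_cal_full <- relative_rmse(rmse_tbl$rmse_cal_full, rng_ref)
    rmse_tbl$rel_rmse_pred_full <- relative_rmse(rmse_tbl$rmse_pred_full, rng_ref)
    rmse_tbl$rel_rmse_pred_full_m100 <-
      if (any(m100)) relative_rmse(rmse_tbl$rmse_pred_full_m100, rng_ref)
      else NA_real_
    results[[par]] <- list(datasets = ds, scan = scan, selection = sel,
                           model = model, rmse = rmse_tbl,
                           trajectories = traj)
  }
  pca <- lapply(list(scatter = prep_scatter, fluorescence = prep_fl),
                function(prep) pca_on_experiment(prep, experiment))
  manifest <- list(
    experiment_id = experiment$experiment_id,
    seed = cfg$seed,
    include_scatter = cfg$include_scatter,
    parameters = cfg$parameters,
    L_max = cfg$L_max,
    calibration_conditions = cal_ids,
    package_version = as.character(utils::packageVersion("eemferm")),
    r_version = R.version.string)
  run <- structure(list(results = results, pca = pca,
                        experiment = experiment, manifest = manifest),
                   class = "eemferm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

pca_on_experiment <- function(prep, experiment, n_pc = 3) {
  blank_ids <- experiment$conditions$condition_id[
    experiment$conditions$role == "blank"]
  rows <- list(); meta <- list()
  for (s in prep) {
    if (s$condition_id %in% blank_ids) next
    keep <- which(series_times(s) <= experiment$t_max_model + 1e-9)
    for (k in keep) {
      uf <- unfold_to_features(s$measurements[[k]])
      rows[[length(rows) + 1L]] <- uf$values
      meta[[length(meta) + 1L]] <- data.frame(
        well = s$well_id, condition = s$condition_id,
        time = s$measurements[[k]]$time, stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, rows)
  fit <- pca_fit(X, n_pc = min(n_pc, nrow(X) - 1L, ncol(X)))
  list(fit = fit, scores = cbind(do.call(rbind, meta),
                                 as.data.frame(fit$scores)),
       total_intensity = rowSums(X))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rmse_all <- do.call(rbind, lapply(run$results, `[[`, "rmse"))
  data.table::fwrite(rmse_all, file.path(out_dir, "rmse_summary.csv"))
  for (par in names(run$results)) {
    r <- run$results[[par]]
    scan <- as.data.frame(r$scan)
    scan$selected <- scan$n_lv == r$selection$n_lv
    data.table::fwrite(scan, file.path(out_dir, paste0("lv_scan_", par, ".csv")))
    data.table::fwrite(r$trajectories,
                       file.path(out_dir, paste0("trajectories_", par, ".csv")))
  }
  for (v in names(run$pca)) {
    data.table::fwrite(run$pca[[v]]$scores,
                       file.path(out_dir, paste0("pca_scores_", v, ".csv")))
  }
  jsonlite::write_json(run$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.eemferm_run <- function(x, ...) {
  cat("Pipeline run:", x$manifest$experiment_id, "\n")
  print(do.call(rbind, lapply(x$results, `[[`, "rmse")), row.names = FALSE)
  invisible(x)
}

#' Compare relative prediction errors across runs
#'
#' Builds a tidy comparison of the relative RMSE variants (full and -100%)
#' per experiment and parameter, the cross-experiment summary view of the
#' workflow.
#'
#' @param runs List of `eemferm_run` objects (>= 2, or 1 compared with
#'   itself).
#' @return Data.frame `experiment, parameter, variant, rel_rmse_pct,
#'   n_lv`.
#' @export
compare_runs <- function(runs) {
  if (inherits(runs, "eemferm_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L)
  pars <- lapply(runs, function(r) sort(names(r$results)))
  if (length(unique(vapply(pars, paste, character(1), collapse = ","))) != 1L)
    stop("runs model different parameter sets")
  rows <- list()
  for (r in runs) {
    for (par in names(r$results)) {
      tb <- r$results[[par]]$rmse
      for (v in c("full", "m100")) {
        val <- if (v == "full") tb$rel_rmse_pred_full else
          tb$rel_rmse_pred_full_m100
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = r$manifest$experiment_id, parameter = par,
          variant = v, rel_rmse_pct = val, n_lv = tb$n_lv,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
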