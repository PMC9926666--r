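# Mechanistic synthetic-data generator: batch growth on glycerol under
# secondary substrate (Mg/K/PO4) limitation, the resulting EEM spectra,
# offline sample tables and headspace pO2 traces. The kinetic scheme is
# this package's own minimal mechanism reproducing the qualitative phases
# of such cultivations (exponential growth -> linear growth under
# limitation -> cessation at glycerol depletion; GFP derepression near
# depletion; pH dip and slow recovery); it is a test-bed, not a fitted
# model of any particular organism.

GLYCEROL_MM <- 92.09  # g/mol

#' Media dilution calculator
#'
#' Concentration of the limited secondary substrate obtained by mixing the
#' basal medium with a medium lacking that substrate, rounded half-up to
#' the printing convention of supplementation tables: two decimals below
#' 10 mg/L, one decimal otherwise.
#'
#' @param fraction Fraction of full supplementation in `[0, 1]`.
#' @param full_conc_mg_L Full-supplementation concentration, mg/L.
#' @return Concentration in mg/L at printed precision.
#' @examples
#' media_design(0.018, 295.8)  # 5.32
#' media_design(0.35, 697.9)   # 244.3
#' @export
media_design <- function(fraction, full_conc_mg_L) {
  stopifnot(all(fraction >= 0), all(fraction <= 1), all(full_conc_mg_L > 0))
  x <- fraction * full_conc_mg_L
  round_half_up <- function(v, digits) floor(v * 10^digits + 0.5) / 10^digits
  ifelse(x < 10, round_half_up(x, 2L), round_half_up(x, 1L))
}

#' Cell dry weight from optical density
#'
#' Linear OD600 correlation, `cdw = slope * od600 + intercept`.
#'
#' @param od600 Optical density at 600 nm, >= 0.
#' @param slope g/L per OD unit.
#' @param intercept g/L offset (default 0).
#' @return CDW in g/L.
#' @export
cdw_from_od600 <- function(od600, slope, intercept = 0) {
  stopifnot(all(od600 >= 0))
  out <- slope * od600 + intercept
  if (any(out < 0)) stop("negative CDW from OD600 correlation")
  out
}

#' Kinetic parameters of the batch-culture mechanism
#'
#' Defaults describe glycerol batch growth of a methylotrophic yeast in
#' buffered mineral medium. `mu_max` and `yos` were calibrated once so
#' that the fully supplemented magnesium culture peaks near 34.5 mmol/L/h
#' OTR at about 22.3 h. `yield_xm` encodes the elemental biomass content
#' of the limited substrate and therefore differs per substrate.
#'
#' @param mu_max Maximum specific growth rate, 1/h.
#' @param ks_glycerol Monod constant for glycerol, g/L.
#' @param yield_xs Biomass yield on glycerol, gX/gS.
#' @param yield_xm Biomass yield on the limited secondary substrate,
#'   gX per mg.
#' @param s0 Initial glycerol, g/L.
#' @param m0 Initial secondary substrate, mg/L.
#' @param x0 Inoculation CDW, g/L.
#' @param limited_growth_rate Residual specific growth rate after
#'   secondary-substrate depletion, 1/h (applied to the biomass present and
#'   scaled by glycerol saturation; small against `mu_max`, so biomass
#'   accretion looks linear on the cultivation time scale).
#' @param maintenance_qs Maintenance glycerol uptake under limitation,
#'   gS/gX/h.
#' @param gfp_derepression_k Glycerol concentration of half-maximal
#'   promoter derepression, g/L.
#' @param gfp_rate GFP accumulation rate, a.u. per (gX/L) per h at full
#'   derepression.
#' @param gfp_limitation_mode GFP behaviour under secondary limitation:
#'   `"stall"`, `"continue"` or `"burst"`.
#' @param gfp_burst_factor Amplification of the GFP rate in `"burst"` mode.
#' @param ph0 Initial medium pH.
#' @param ph_drop_per_gX pH decrease per g/L biomass formed (ammonium
#'   uptake against the MES buffer).
#' @param ph_recovery_rate First-order pH relaxation toward `ph0` after
#'   glycerol depletion, 1/h.
#' @param yos Respiratory oxygen demand, mol O2 per mol glycerol consumed.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(mu_max = 0.24, ks_glycerol = 0.1,
                           yield_xs = 0.5, yield_xm = 0.33,
                           s0 = 12, m0 = 295.8, x0 = 0.03,
                           limited_growth_rate = 0.03,
                           maintenance_qs = 0.02,
                           gfp_derepression_k = 0.5, gfp_rate = 100,
                           gfp_limitation_mode = c("stall", "continue", "burst"),
                           gfp_burst_factor = 5,
                           ph0 = 6.0, ph_drop_per_gX = 0.09,
                           ph_recovery_rate = 0.1, yos = 1.3) {
  gfp_limitation_mode <- match.arg(gfp_limitation_mode)
  stopifnot(mu_max > 0, ks_glycerol > 0, yield_xs > 0, yield_xm > 0,
            s0 >= 0, m0 >= 0, x0 >= 0, limited_growth_rate >= 0,
            maintenance_qs >= 0, gfp_derepression_k > 0, gfp_rate >= 0,
            ph_recovery_rate >= 0, yos > 0)
  structure(as.list(environment()), class = "kinetic_params")
}

# phase rate laws; state y = c(X, S, M, G)
batch_rates <- function(y, p, phase) {
  X <- y[1]; S <- y[2]
  sat <- S / (p$ks_glycerol + S)
  derep <- p$gfp_derepression_k / (p$gfp_derepression_k + S)
  mode_f <- switch(p$gfp_limitation_mode,
                   stall = 0, continue = 1, burst = p$gfp_burst_factor)
  if (phase == 1L) {
    mu <- p$mu_max * sat
    dX <- mu * X
    c(dX, -mu * X / p$yield_xs, -mu * X / p$yield_xm,
      p$gfp_rate * X * derep)
  } else if (phase == 2L) {
    # residual growth scales with the biomass built before the limitation
    # hit, so a lower supplementation can never overtake a higher one
    dX <- p$limited_growth_rate * X * sat
    c(dX, -dX / p$yield_xs - p$maintenance_qs * X, 0,
      p$gfp_rate * X * derep * mode_f)
  } else {
    c(0, 0, 0, 0)
  }
}

#' Simulate one batch cultivation
#'
#' Deterministic integration (lsoda, piecewise across phase boundaries) of
#' the three-phase batch mechanism: (1) unrestricted Monod growth while
#' both glycerol S and the secondary substrate M remain, (2) slow linear
#' growth plus maintenance consumption after M depletes, (3) full
#' cessation once S depletes, after which the pH relaxes back toward its
#' initial value. GFP accumulates with promoter derepression at low
#' glycerol, modulated under limitation by the substrate-specific mode.
#'
#' @param params A [kinetic_params()].
#' @param duration Hours.
#' @param dt Output grid step, hours.
#' @return Object of class `bioprocess_trajectory`: data.frame with
#'   columns `time, X, S, M, G, pH, OTR, pO2` (OTR in mmol/L/h; pO2 the
#'   nominal end-of-measuring-phase headspace value, % air saturation).
#' @export
simulate_batch <- function(params, duration, dt = 0.05) {
  stopifnot(inherits(params, "kinetic_params"), duration > 0, dt > 0)
  p <- params
  t_grid <- seq(0, duration, by = dt)
  if (abs(t_grid[length(t_grid)] - duration) > 1e-9)
    t_grid <- c(t_grid, duration)
  state <- c(X = p$x0, S = p$s0, M = p$m0, G = 0)
  out <- matrix(NA_real_, length(t_grid), 4,
                dimnames = list(NULL, c("X", "S", "M", "G")))
  phase_at <- integer(length(t_grid))
  phase <- if (p$m0 <= 0) 2L else 1L
  if (p$s0 <= 0) phase <- 3L
  t_cur <- 0
  i_next <- 1L
  t_s_depleted <- NA_real_
  while (i_next <= length(t_grid)) {
    if (phase == 3L || p$x0 == 0) {
      idx <- i_next:length(t_grid)
      out[idx, ] <- matrix(state, length(idx), 4, byrow = TRUE)
      phase_at[idx] <- phase
      break
    }
    rhs <- function(t, y, parms) list(batch_rates(y, p, phase))
    root <- function(t, y, parms) {
      if (phase == 1L) c(y[2], y[3]) else y[2]
    }
    times <- unique(c(t_cur, t_grid[t_grid > t_cur + 1e-12]))
    sol <- deSolve::lsoda(state, times, rhs, parms = NULL,
                          rootfunc = root, atol = 1e-10, rtol = 1e-10)
    troot <- attr(sol, "troot")
    sol_t <- sol[, 1]
    hit <- match(round(t_grid, 10), round(sol_t, 10))
    filled <- which(!is.na(hit) & seq_along(t_grid) >= i_next)
    out[filled, ] <- sol[hit[filled], -1, drop = FALSE]
    phase_at[filled] <- phase
    if (length(troot) == 0L || is.null(troot)) break  # ran to duration
    # phase transition: clamp the depleted pool and continue
    state <- sol[nrow(sol), -1]
    state[state < 0] <- 0
    t_cur <- sol_t[length(sol_t)]
    i_next <- if (length(filled)) max(filled) + 1L else i_next
    if (phase == 1L && state[3] <= 1e-12 && state[2] > 1e-12) {
      state[3] <- 0
      phase <- 2L
    } else {
      state[2] <- 0
      t_s_depleted <- t_cur
      phase <- 3L
    }
  }
  if (anyNA(out)) stop("integration failed to cover the output grid")
  if (any(out < -1e-6)) stop("negative state encountered during integration")
  out[out < 0] <- 0
  # pH: biomass-linked dip while S > 0, slow first-order recovery after
  ph <- p$ph0 - p$ph_drop_per_gX * (out[, "X"] - p$x0)
  if (!is.na(t_s_depleted)) {
    after <- t_grid >= t_s_depleted
    ph_dep <- p$ph0 - p$ph_drop_per_gX * (out[after, "X"][1] - p$x0)
    ph[after] <- p$ph0 + (ph_dep - p$ph0) *
      exp(-p$ph_recovery_rate * (t_grid[after] - t_s_depleted))
  }
  # OTR from the instantaneous glycerol consumption rate
  qs_tot <- vapply(seq_along(t_grid), function(i)
    -batch_rates(out[i, ], p, phase_at[i])[2], numeric(1))
  otr <- p$yos * qs_tot * 1000 / GLYCEROL_MM
  traj <- data.frame(time = t_grid, X = out[, "X"], S = out[, "S"],
                     M = out[, "M"], G = out[, "G"], pH = ph, OTR = otr,
                     pO2 = NA_real_)
  traj$pO2 <- headspace_po2_pct(otr)
  class(traj) <- c("bioprocess_trajectory", "data.frame")
  attr(traj, "params") <- p
  traj
}

# nominal % air saturation at the end of a 10 min stop-flow measuring
# phase in a 48-well plate (vg 2.4 mL, vl 0.8 mL, 30 C)
headspace_po2_pct <- function(otr, vg = 0.0024, vl = 0.0008,
                              temperature = 303.15, t_meas = 10 / 60) {
  dp <- otr / 1000 * vl * R_GAS * temperature / vg * t_meas  # bar
  pmax(0, 100 * (O2_FRACTION_AIR - dp) / O2_FRACTION_AIR)
}

#' Fluorophore component of the spectral forward model
#'
#' Each component contributes a separable Gaussian peak on the EEM grid
#' whose amplitude follows one culture-state variable.
#'
#' @param name Label.
#' @param ex_center,em_center Peak position, nm (`em_center >= ex_center`).
#' @param ex_sigma,em_sigma Gaussian widths, nm (> 0).
#' @param amplitude_source `"gfp"`, `"biomass"`, `"active_biomass"` or
#'   `"constant"`.
#' @param gain Intensity units per source unit.
#' @return A list of class `fluorophore`.
#' @export
fluorophore <- function(name, ex_center, em_center, ex_sigma, em_sigma,
                        amplitude_source = c("gfp", "biomass",
                                             "active_biomass", "constant"),
                        gain = 1) {
  amplitude_source <- match.arg(amplitude_source)
  stopifnot(ex_sigma > 0, em_sigma > 0, em_center >= ex_center)
  structure(list(name = name, ex_center = ex_center, em_center = em_center,
                 ex_sigma = ex_sigma, em_sigma = em_sigma,
                 amplitude_source = amplitude_source, gain = gain),
            class = "fluorophore")
}

#' Default fluorophore library
#'
#' GFP (readout pixel 420/530 nm), NADH (340/450, tracking actively
#' growing biomass) and flavins (450/530, tracking total biomass).
#' Centers are conventional literature positions chosen to place signal
#' under the standard readout pixels; widths are configuration, not
#' measured truth.
#'
#' @return List of [fluorophore()]s.
#' @export
default_fluorophores <- function() {
  list(
    fluorophore("GFP", 420, 530, 40, 35, "gfp", gain = 1),
    fluorophore("NADH", 340, 450, 25, 40, "active_biomass", gain = 150),
    fluorophore("flavins", 450, 530, 25, 35, "biomass", gain = 120)
  )
}

#' Synthesize one EEM spectrum from a culture state
#'
#' Sum of separable Gaussian fluorophore peaks, a biomass-driven
#' scattered-light ridge along the ex = em diagonal (saturating in
#' biomass), a flat baseline and heteroscedastic Gaussian noise
#' `N(0, sigma_floor + sigma_rel * signal)`, clipped at zero. Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param state Named list/vector with `gfp`, `biomass`, `active_biomass`.
#' @param components List of [fluorophore()]s.
#' @param grid An `eem_grid`.
#' @param well_id,time Labels for the resulting measurement.
#' @param scatter List `a_sat` (intensity at biomass saturation), `k_x`
#'   (half-saturation CDW, g/L), `sigma_nm` (ridge width).
#' @param baseline Flat background intensity.
#' @param noise List `sigma_floor`, `sigma_rel`; set both 0 for
#'   noise-free spectra.
#' @return An `eem_measurement`.
#' @export
synthesize_eem <- function(state, components, grid, well_id = "A1", time = 0,
                           scatter = list(a_sat = 4000, k_x = 15, sigma_nm = 6),
                           baseline = 50,
                           noise = list(sigma_floor = 2, sigma_rel = 0.01)) {
  stopifnot(inherits(grid, "eem_grid"))
  d <- dim_eem(grid)
  signal <- matrix(baseline, d[1], d[2])
  for (cm in components) {
    amp <- cm$gain * switch(cm$amplitude_source,
                            gfp = state$gfp, biomass = state$biomass,
                            active_biomass = state$active_biomass,
                            constant = 1)
    if (amp == 0) next
    ex_prof <- exp(-(grid$excitation - cm$ex_center)^2 / (2 * cm$ex_sigma^2))
    em_prof <- exp(-(grid$emission - cm$em_center)^2 / (2 * cm$em_sigma^2))
    signal <- signal + amp * outer(ex_prof, em_prof)
  }
  if (state$biomass > 0 && scatter$a_sat > 0) {
    off <- offset_matrix(grid)
    amp <- scatter$a_sat * state$biomass / (scatter$k_x + state$biomass)
    signal <- signal + amp * exp(-off^2 / (2 * scatter$sigma_nm^2))
  }
  if (noise$sigma_floor > 0 || noise$sigma_rel > 0) {
    sd_px <- noise$sigma_floor + noise$sigma_rel * signal
    signal <- signal + matrix(stats::rnorm(length(signal), 0, sd_px),
                              d[1], d[2])
  }
  signal[signal < 0] <- 0
  eem_measurement(well_id, time, signal, grid)
}

#' Simulation configuration and experiment presets
#'
#' Study conditions of the three limitation experiments: the condition
#' ladders mirror the published supplementation tables (fractions of the
#' full concentration: Mg 295.8, K 2017.3, PO4 697.9 mg/L), duplicate
#' wells per condition, spectra every 0.5 h, offline sampling every 1.5 h,
#' sparse-schedule gap 6 h (Mg) or 5 h (K, PO4), and analysis cutoffs of
#' none (Mg), 43 h (K) and 34.5 h (PO4).
#'
#' @param preset `"Mg"`, `"K"` or `"PO4"`.
#' @param seed Integer seed; mandatory (every stochastic output derives
#'   from it).
#' @param replicates Wells per condition.
#' @param grid EEM grid for the spectra.
#' @param noise Noise model: spectral `sigma_floor`/`sigma_rel`, offline
#'   `glycerol_cv`, `cdw_cv`, `ph_sd`, and headspace `po2_sd`
#'   (% air saturation). Set all 0 for noise-free data.
#' @param components Fluorophore library.
#' @param kinetics Baseline [kinetic_params()]; per-condition `m0`, `x0`
#'   and the GFP limitation mode are filled in from the preset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(preset = c("Mg", "K", "PO4"), seed,
                       replicates = 2, grid = default_grid("caption"),
                       noise = list(sigma_floor = 2, sigma_rel = 0.01,
                                    glycerol_cv = 0.002, cdw_cv = 0.03,
                                    ph_sd = 0.02, po2_sd = 0.1),
                       components = default_fluorophores(),
                       kinetics = kinetic_params()) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("a seed is mandatory for synthetic experiments")
  ladder <- switch(preset,
    Mg = data.frame(
      fraction = c(1, 1, 1, 0.018, 0.014, 0.008, 0.004, 0),
      cdw_t0 = c(0.03, 0.06, 0.11, rep(0.03, 5)),
      role = c("prediction", "calibration", "prediction", "prediction",
               "prediction", "prediction", "calibration", "prediction")),
    K = data.frame(
      fraction = c(1, 0.05, 0.04, 0.03, 0.025, 0.0175, 0.0125, 0.01),
      cdw_t0 = rep(0.03, 8),
      role = c("prediction", "calibration", "prediction", "prediction",
               "prediction", "prediction", "prediction", "calibration")),
    PO4 = data.frame(
      fraction = c(1, 0.35, 0.2, 0.15, 0.125, 0.1, 0.075, 0),
      cdw_t0 = rep(0.03, 8),
      role = c("prediction", "calibration", "prediction", "prediction",
               "prediction", "prediction", "calibration", "prediction"))
  )
  full_conc <- switch(preset, Mg = 295.8, K = 2017.3, PO4 = 697.9)
  yield_xm <- switch(preset, Mg = 0.33, K = 0.04, PO4 = 0.02)
  gfp_mode <- switch(preset, Mg = "stall", K = "stall", PO4 = "burst")
  duration <- switch(preset, Mg = 30, K = 45, PO4 = 36)
  t_max_model <- switch(preset, Mg = Inf, K = 43, PO4 = 34.5)
  sparse_gap <- switch(preset, Mg = 6, K = 5, PO4 = 5)
  structure(list(preset = preset, full_conc = full_conc, ladder = ladder,
                 yield_xm = yield_xm, gfp_mode = gfp_mode,
                 replicates = as.integer(replicates), cadence = 0.5,
                 duration = duration, t_max_model = t_max_model,
                 offline_interval_h = 1.5, sparse_min_gap_h = sparse_gap,
                 n_blanks = 2L, grid = grid, noise = noise,
                 components = components, kinetics = kinetics,
                 vg = 0.0024, vl = 0.0008, temperature = 303.15,
                 seed = as.integer(seed)),
            class = "sim_config")
}

interp_state <- function(traj, t) {
  f <- function(col) stats::approx(traj$time, traj[[col]], xout = t,
                                   rule = 2)$y
  list(X = f("X"), S = f("S"), G = f("G"), pH = f("pH"),
       glycerol = f("S"), cdw = f("X"), OTR = f("OTR"))
}

#' Generate a complete synthetic plate experiment
#'
#' Simulates every condition of the preset ladder, attaches duplicate
#' wells with independent measurement noise, and emits spectra at the
#' measurement cadence, a full-schedule offline table with realistic
#' analytical noise, per-well stop-flow headspace pO2 traces consistent
#' with the simulated OTR, and non-inoculated blank wells. All randomness
#' derives from `cfg$seed`; rerunning with the same configuration gives
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @return A [plate_experiment()].
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ladder <- cfg$ladder
  cond_ids <- sprintf("%s_%03.1fpct_x%03g", cfg$preset,
                      100 * ladder$fraction, ladder$cdw_t0)
  conc <- media_design(ladder$fraction, cfg$full_conc)
  conds <- culture_conditions(
    condition_id = c(cond_ids, "blank"),
    substrate_fraction = c(ladder$fraction, 1),
    substrate_conc = c(conc, cfg$full_conc),
    cdw_t0 = c(ladder$cdw_t0, 0),
    role = c(ladder$role, "blank"))
  spec_times <- seq(0, cfg$duration, by = cfg$cadence)
  off_times <- seq(0, cfg$duration, by = cfg$offline_interval_h)
  nz <- cfg$noise
  well_names <- paste0(rep(LETTERS[1:6], each = 8), rep(1:8, 6))
  well_k <- 0L
  spectra <- list(); po2 <- list(); well_rows <- list(); off_rows <- list()
  for (ci in seq_len(nrow(conds))) {
    cid <- conds$condition_id[ci]
    is_blank <- conds$role[ci] == "blank"
    kp <- cfg$kinetics
    kp$m0 <- conds$substrate_conc[ci]
    kp$x0 <- conds$cdw_t0[ci]
    kp$yield_xm <- cfg$yield_xm
    kp$gfp_limitation_mode <- cfg$gfp_mode
    traj <- simulate_batch(kp, cfg$duration, dt = 0.05)
    st_spec <- interp_state(traj, spec_times)
    n_wells <- if (is_blank) cfg$n_blanks else cfg$replicates
    for (r in seq_len(n_wells)) {
      well_k <- well_k + 1L
      w <- well_names[well_k]
      meas <- vector("list", length(spec_times))
      for (k in seq_along(spec_times)) {
        state <- list(
          gfp = st_spec$G[k], biomass = st_spec$X[k],
          active_biomass = st_spec$X[k] *
            st_spec$S[k] / (st_spec$S[k] + kp$ks_glycerol))
        meas[[k]] <- synthesize_eem(
          state, cfg$components, cfg$grid, well_id = w,
          time = spec_times[k],
          noise = list(sigma_floor = nz$sigma_floor,
                       sigma_rel = nz$sigma_rel))
      }
      spectra[[w]] <- spectrum_series(w, cid, meas, cadence = cfg$cadence)
      po2[[w]] <- simulate_po2_trace(w, spec_times, st_spec$OTR, cfg)
      well_rows[[well_k]] <- data.frame(well_id = w, condition_id = cid,
                                        stringsAsFactors = FALSE)
    }
    if (!is_blank) {
      st_off <- interp_state(traj, off_times)
      gly <- st_off$S * (1 + stats::rnorm(length(off_times), 0, nz$glycerol_cv))
      cdw <- st_off$X * (1 + stats::rnorm(length(off_times), 0, nz$cdw_cv))
      ph <- st_off$pH + stats::rnorm(length(off_times), 0, nz$ph_sd)
      off_rows[[length(off_rows) + 1L]] <- data.frame(
        condition = cid, time_h = off_times,
        glycerol_gL = pmax(0, gly), cdw_gL = pmax(0, cdw), pH = ph,
        stringsAsFactors = FALSE)
    }
  }
  offline <- offline_table(do.call(rbind, off_rows), schedule = "full")
  exp <- plate_experiment(
    experiment_id = paste0("synthetic_", cfg$preset, "_seed", cfg$seed),
    limited_substrate = cfg$preset, conditions = conds,
    well_map = do.call(rbind, well_rows), spectra = spectra,
    offline = offline, po2 = po2,
    t_max_model = min(cfg$t_max_model, max(spec_times)),
    full_conc = cfg$full_conc)
  attr(exp, "sparse_min_gap_h") <- cfg$sparse_min_gap_h
  exp
}

# stop-flow headspace pO2 trace for one well: per measurement cycle a
# 10 min sealed measuring phase (6 points) whose decline slope encodes the
# OTR, separated by a flushing point back at air saturation
simulate_po2_trace <- function(well_id, cycle_times, otr, cfg) {
  n_pts <- 6L
  tau <- seq(0, 10 / 60, length.out = n_pts)
  times <- c(); vals <- c(); phase <- c()
  for (k in seq_along(cycle_times)) {
    slope_bar <- otr[k] / 1000 * cfg$vl * R_GAS * cfg$temperature / cfg$vg
    p_bar <- O2_FRACTION_AIR - slope_bar * tau
    pct <- pmax(0, 100 * p_bar / O2_FRACTION_AIR +
                  stats::rnorm(n_pts, 0, cfg$noise$po2_sd))
    times <- c(times, cycle_times[k] + tau, cycle_times[k] + 0.25)
    vals <- c(vals, pct, 100)
    phase <- c(phase, rep("measuring", n_pts), "flushing")
  }
  keep <- !duplicated(round(times, 9))
  po2_trace(well_id, times[keep], vals[keep], phase[keep],
            unit = "percent_air_sat")
}
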