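# Shared fixtures: small grids and a reduced-resolution simulation
# configuration that keeps the full condition ladder and dynamics but uses
# a coarse spectral grid, so whole-plate tests run in seconds.

toy_grid <- function() eem_grid(c(300, 400), c(350, 355, 360))

toy_measurement <- function(vals = matrix(1:6, 2, 3), well = "A1", t = 0,
                            grid = toy_grid()) {
  eem_measurement(well, t, vals, grid)
}

# coarse grid covering the scatter diagonal, the GFP readout region and
# the NADH/flavin peaks
small_grid <- function() eem_grid(seq(300, 600, by = 50), seq(310, 650, by = 5))

# preprocessing matched to the coarse grid (native emission step 5 nm)
small_prep <- function(include_scatter = TRUE)
  preprocess_config(smooth_window_px = 5, target_em_step = 10,
                    include_scatter = include_scatter)

small_sim <- function(seed, preset = "Mg", ...) {
  cfg <- sim_config(preset, seed = seed, grid = small_grid(), ...)
  cfg
}

# one noise-free series on a grid, straight from a simulated trajectory
noise_free_series <- function(kp = kinetic_params(), grid = default_grid(),
                              duration = 30, cadence = 1, well = "W1") {
  traj <- simulate_batch(kp, duration)
  tt <- seq(0, duration, by = cadence)
  st <- list(
    X = approx(traj$time, traj$X, tt)$y,
    S = approx(traj$time, traj$S, tt)$y,
    G = approx(traj$time, traj$G, tt)$y)
  meas <- lapply(seq_along(tt), function(k) {
    synthesize_eem(
      list(gfp = st$G[k], biomass = st$X[k],
           active_biomass = st$X[k] * st$S[k] / (st$S[k] + kp$ks_glycerol)),
      default_fluorophores(), grid, well_id = well, time = tt[k],
      noise = list(sigma_floor = 0, sigma_rel = 0))
  })
  list(series = spectrum_series(well, "c1", meas, cadence),
       state = st, times = tt, traj = traj)
}
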