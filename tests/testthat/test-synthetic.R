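test_that("media dilution reproduces the printed supplementation tables", {
  # magnesium ladder (full 295.8 mg/L)
  expect_equal(media_design(1, 295.8), 295.8)
  expect_equal(media_design(c(0.018, 0.014, 0.008, 0.004, 0), 295.8),
               c(5.32, 4.14, 2.37, 1.18, 0))
  # potassium ladder (full 2017.3 mg/L)
  expect_equal(media_design(c(0.05, 0.04, 0.03, 0.025, 0.0175, 0.0125, 0.01),
                            2017.3),
               c(100.9, 80.7, 60.5, 50.4, 35.3, 25.2, 20.2))
  # phosphate ladder (full 697.9 mg/L)
  expect_equal(media_design(c(0.35, 0.2, 0.15, 0.125, 0.1, 0.075), 697.9),
               c(244.3, 139.6, 104.7, 87.2, 69.8, 52.3))
})

test_that("cdw-od600 correlation is linear and invertible", {
  expect_equal(cdw_from_od600(0, 0.27), 0)
  od <- c(0.1, 1, 7.3)
  cdw <- cdw_from_od600(od, 0.27, 0.01)
  expect_lt(max(abs((cdw - 0.01) / 0.27 - od)), 1e-12)
  expect_equal(cdw_from_od600(od, 0.54), 2 * cdw_from_od600(od, 0.27))
  expect_error(cdw_from_od600(1, 0.27, -1), "negative")
})

test_that("no inoculum means no dynamics", {
  kp <- kinetic_params(x0 = 0)
  tr <- simulate_batch(kp, 10, dt = 0.5)
  expect_true(all(tr$X == 0))
  expect_true(all(tr$S == kp$s0))
  expect_true(all(tr$G == 0))
  expect_true(all(tr$OTR == 0))
  expect_true(all(tr$pH == kp$ph0))
})

test_that("glycerol-biomass mass balance closes", {
  # maintenance off, full supplementation: exact yield coupling
  kp <- kinetic_params(maintenance_qs = 0)
  tr <- simulate_batch(kp, 30)
  gain <- tail(tr$X, 1) - kp$x0
  used <- kp$yield_xs * (kp$s0 - tail(tr$S, 1))
  expect_lt(abs(used - gain), 1e-6)
  # independent closure: trapezoidal O2 uptake equals yos x glycerol used
  o2_trap <- sum(diff(tr$time) * (head(tr$OTR, -1) + tail(tr$OTR, -1)) / 2)
  o2_expected <- kp$yos * (kp$s0 - tail(tr$S, 1)) * 1000 / 92.09
  expect_lt(abs(o2_trap - o2_expected) / o2_expected, 0.02)
  # with maintenance on, biomass gain never exceeds the yield bound
  kpm <- kinetic_params(m0 = 2.37)
  trm <- simulate_batch(kpm, 30)
  expect_gte(kpm$yield_xs * (kpm$s0 - tail(trm$S, 1)) -
               (tail(trm$X, 1) - kpm$x0), -1e-6)
})

test_that("full magnesium preset hits the configured OTR peak anchors", {
  tr <- simulate_batch(kinetic_params(), 30)
  i <- which.max(tr$OTR)
  expect_lt(abs(tr$OTR[i] - 34.5) / 34.5, 0.15)
  expect_lt(abs(tr$time[i] - 22.3) / 22.3, 0.15)
})

test_that("trajectories respect monotonicity and the limitation ladder", {
  fractions <- c(1, 0.018, 0.014, 0.008, 0.004, 0)
  finals <- vapply(fractions, function(f) {
    kp <- kinetic_params(m0 = media_design(f, 295.8))
    tr <- simulate_batch(kp, 30)
    expect_true(all(diff(tr$S) <= 1e-9))        # glycerol never rises
    expect_true(all(diff(tr$X) >= -1e-9))       # biomass never falls
    expect_true(all(diff(tr$G) >= -1e-9))       # GFP accumulates
    expect_true(all(tr$M >= -1e-12))
    tail(tr$X, 1)
  }, numeric(1))
  # lower supplementation gives lower or equal final biomass
  expect_true(all(diff(rev(finals)) >= -1e-9))
})

test_that("GFP limitation modes: stall freezes, burst amplifies", {
  kp_stall <- kinetic_params(m0 = 2.37, gfp_limitation_mode = "stall")
  kp_cont <- kinetic_params(m0 = 2.37, gfp_limitation_mode = "continue")
  kp_burst <- kinetic_params(m0 = 2.37, gfp_limitation_mode = "burst")
  g_end <- vapply(list(kp_stall, kp_cont, kp_burst), function(k)
    tail(simulate_batch(k, 30)$G, 1), numeric(1))
  expect_lt(g_end[1], g_end[2])
  expect_lt(g_end[2], g_end[3])
  # under stall, GFP is flat after the limitation onset
  tr <- simulate_batch(kp_stall, 30)
  onset <- min(which(tr$M == 0))
  expect_equal(tr$G[onset], tail(tr$G, 1), tolerance = 1e-9)
})

test_that("pH dips with biomass and recovers after glycerol depletion", {
  kp <- kinetic_params()
  tr <- simulate_batch(kp, 30)
  dep <- min(which(tr$S == 0))
  expect_lt(min(tr$pH), kp$ph0)
  expect_lte(abs(which.min(tr$pH) - dep), 1)     # minimum at depletion
  post <- tr$pH[dep:nrow(tr)]
  expect_true(all(diff(post) >= -1e-12))          # monotone recovery
  expect_lt(tail(post, 1), kp$ph0 + 1e-9)         # toward, not past, ph0
})

test_that("synthesized spectra match the closed-form component model", {
  g <- small_grid()
  state <- list(gfp = 500, biomass = 3, active_biomass = 2)
  # all gains and noise zero: flat baseline
  flat <- synthesize_eem(state, list(), g, baseline = 7,
                         scatter = list(a_sat = 0, k_x = 15, sigma_nm = 6),
                         noise = list(sigma_floor = 0, sigma_rel = 0))
  expect_true(all(flat$intensities == 7))
  # a single GFP component evaluated at its peak equals gain * G + baseline
  comp <- fluorophore("gfp_only", 400, 530, 30, 30, "gfp", gain = 2)
  m <- synthesize_eem(state, list(comp), g, baseline = 7,
                      scatter = list(a_sat = 0, k_x = 15, sigma_nm = 6),
                      noise = list(sigma_floor = 0, sigma_rel = 0))
  i <- which(g$excitation == 400); j <- which(g$emission == 530)
  expect_equal(m$intensities[i, j], 2 * 500 + 7, tolerance = 1e-12)
  # scatter ridge concentrates within 3 sigma of the diagonal
  sc <- synthesize_eem(list(gfp = 0, biomass = 3, active_biomass = 0),
                       list(), g, baseline = 0,
                       scatter = list(a_sat = 1000, k_x = 15, sigma_nm = 6),
                       noise = list(sigma_floor = 0, sigma_rel = 0))
  off <- abs(outer(g$excitation, g$emission, function(a, b) b - a))
  inside <- sum(sc$intensities[off <= 18])
  expect_gt(inside / sum(sc$intensities), 0.99)
})

test_that("single-pixel channels track their driving state variables", {
  nf <- noise_free_series(duration = 28, cadence = 1)
  sc <- extract_channel(nf$series, 600, 600)
  gfp <- extract_channel(nf$series, 420, 530)
  expect_equal(cor(sc$intensity, nf$state$X, method = "spearman"), 1)
  expect_equal(cor(gfp$intensity, nf$state$G, method = "spearman"), 1)
})

test_that("experiment generation is seed-deterministic", {
  cfg <- small_sim(seed = 11)
  cfg$duration <- 3
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1, e2)
  cfg2 <- small_sim(seed = 12)
  cfg2$duration <- 3
  e3 <- generate_experiment(cfg2)
  expect_false(identical(e1$spectra$A1$measurements[[1]]$intensities,
                         e3$spectra$A1$measurements[[1]]$intensities))
})

test_that("zero noise puts offline samples exactly on the trajectories", {
  cfg <- small_sim(seed = 5)
  cfg$duration <- 12
  cfg$noise <- list(sigma_floor = 0, sigma_rel = 0, glycerol_cv = 0,
                    cdw_cv = 0, ph_sd = 0, po2_sd = 0)
  exp <- generate_experiment(cfg)
  off <- as.data.frame(exp$offline)
  for (ci in seq_len(nrow(exp$conditions))) {
    if (exp$conditions$role[ci] == "blank") next
    cid <- exp$conditions$condition_id[ci]
    kp <- cfg$kinetics
    kp$m0 <- exp$conditions$substrate_conc[ci]
    kp$x0 <- exp$conditions$cdw_t0[ci]
    kp$yield_xm <- cfg$yield_xm
    tr <- simulate_batch(kp, cfg$duration)
    oc <- off[off$condition == cid, ]
    expect_equal(oc$glycerol_gL,
                 approx(tr$time, tr$S, oc$time_h)$y, tolerance = 1e-9)
    expect_equal(oc$cdw_gL,
                 approx(tr$time, tr$X, oc$time_h)$y, tolerance = 1e-9)
    expect_equal(oc$pH,
                 approx(tr$time, tr$pH, oc$time_h)$y, tolerance = 1e-9)
  }
})

test_that("generated experiments are structurally complete", {
  cfg <- small_sim(seed = 6)
  cfg$duration <- 3
  exp <- generate_experiment(cfg)
  expect_s3_class(exp, "plate_experiment")
  expect_equal(nrow(exp$conditions), 9L)  # 8 ladder conditions + blank
  n_wells <- 8L * cfg$replicates + cfg$n_blanks
  expect_length(exp$spectra, n_wells)
  expect_length(exp$po2, n_wells)
  expect_equal(nrow(exp$well_map), n_wells)
  # every series has the full cadence grid
  expect_true(all(vapply(exp$spectra, function(s)
    length(s$measurements) == length(seq(0, cfg$duration, cfg$cadence)),
    logical(1))))
  # blanks carry no biology: spectra are baseline + noise only
  blank_w <- exp$well_map$well_id[exp$well_map$condition_id == "blank"][1]
  bm <- exp$spectra[[blank_w]]$measurements[[1]]
  expect_lt(max(abs(bm$intensities - 50)), 50 * 0.2 + 5 * (2 + 0.01 * 50))
})
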