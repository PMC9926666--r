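grid_mid <- function() eem_grid(c(280, 420), seq(260, 700, by = 4))

rand_measurement <- function(grid, seed = 1) {
  set.seed(seed)
  eem_measurement("A1", 0,
                  matrix(runif(prod(dim_eem(grid)), 0, 100),
                         length(grid$excitation), length(grid$emission)),
                  grid)
}

test_that("emission window keeps [-10, +270] nm relative to excitation", {
  g <- grid_mid()
  m <- restrict_emission_window(rand_measurement(g), c(-10, 270))
  # ex 280 keeps em in [270, 550]
  i <- which(g$excitation == 280)
  kept <- g$emission[m$valid[i, ]]
  expect_equal(range(kept), c(272, 548))  # grid nodes inside [270, 550]
  expect_true(all(kept >= 270 & kept <= 550))
  # retained count per row equals brute-force enumeration
  for (i in seq_along(g$excitation)) {
    n_bf <- sum(vapply(g$emission, function(em) {
      off <- em - g$excitation[i]
      off >= -10 && off <= 270
    }, logical(1)))
    expect_equal(sum(m$valid[i, ]), n_bf)
  }
  # a window wider than the grid is a no-op
  m2 <- restrict_emission_window(rand_measurement(g), c(-1e6, 1e6))
  expect_equal(m2$intensities, rand_measurement(g)$intensities)
  expect_true(all(m2$valid))
})

test_that("scatter masking removes the [-10, +13] nm diagonal band", {
  g <- grid_mid()
  m <- mask_scatter(rand_measurement(g), c(-10, 13))
  i <- which(g$excitation == 420)
  masked_em <- g$emission[!m$valid[i, ]]
  expect_true(all(masked_em >= 410 & masked_em <= 433))
  expect_equal(sum(!m$valid), bf_band_count(g, -10, 13))
  expect_true(all(is.na(m$intensities[!m$valid])))
  # band entirely below the grid's minimum offset: nothing masked
  m2 <- mask_scatter(rand_measurement(g), c(-500, -450))
  expect_true(all(m2$valid))
})

test_that("moving average matches a brute-force windowed mean", {
  g <- eem_grid(300, seq(400, 400 + 49 * 2, by = 2))  # one 50-pixel row
  set.seed(7)
  vals <- matrix(runif(50, 0, 10), 1, 50)
  m <- eem_measurement("A1", 0, vals, g)
  sm <- smooth_emission(m, 25)
  expect_lt(max(abs(sm$intensities[1, ] -
                      bf_moving_average(vals[1, ], rep(TRUE, 50), 25))), 1e-12)
  # with masked pixels the mean is over valid neighbours only
  mm <- m
  mm$valid[1, c(3, 10:14)] <- FALSE
  mm$intensities[!mm$valid] <- NA
  sm2 <- smooth_emission(mm, 25)
  bf <- bf_moving_average(vals[1, ], mm$valid[1, ], 25)
  expect_equal(sm2$intensities[1, ], bf, tolerance = 1e-12)
  expect_true(all(is.na(sm2$intensities[1, !mm$valid[1, ]])))
})

test_that("smoothing identities: window 1 and constant rows", {
  m <- rand_measurement(grid_mid())
  expect_identical(smooth_emission(m, 1), m)
  const <- eem_measurement("A1", 0, matrix(3.5, 2, 111), grid_mid())
  smc <- smooth_emission(const, 25)
  expect_equal(smc$intensities, const$intensities, tolerance = 1e-12)
  # window longer than the row collapses it to its own mean
  g1 <- eem_grid(300, seq(400, 408, by = 2))
  row <- matrix(c(1, 2, 3, 4, 10), 1, 5)
  expect_message(out <- smooth_emission(eem_measurement("A", 0, row, g1), 11),
                 "exceeds")
  expect_equal(drop(out$intensities), rep(mean(row), 5), tolerance = 1e-12)
})

test_that("downsampling rebuilds the axis and averages bins correctly", {
  g <- default_grid("caption")
  set.seed(3)
  vals <- matrix(runif(43 * 983, 0, 100), 43, 983)
  m <- eem_measurement("A1", 0, vals, g)
  dn <- downsample_emission(m, 2)
  em <- g$emission
  expect_equal(length(dn$grid$emission), floor((max(em) - min(em)) / 2) + 1)
  bf <- bf_bin_means(em, vals[17, ], rep(TRUE, 983), 2)
  expect_equal(dn$grid$emission, bf$centers)
  expect_lt(max(abs(dn$intensities[17, ] - bf$means)), 1e-12)
  # target step equal to the native step is the identity
  same <- downsample_emission(m, 0.45)
  expect_equal(same$intensities, vals, tolerance = 1e-12)
  expect_error(downsample_emission(dn, 0.45), "smaller than")
})

test_that("downsampled pixels are masked iff all contributors are masked", {
  g <- eem_grid(300, seq(100, 119, by = 1))
  vals <- matrix(as.numeric(1:20), 1, 20)
  valid <- matrix(TRUE, 1, 20)
  valid[1, 5:8] <- FALSE   # kills bin centered 106 entirely ([105,107): px 105,106)
  vals[1, 5:8] <- NA
  m <- eem_measurement("A", 0, vals, g, valid = valid,
                       check_nonnegative = FALSE)
  dn <- downsample_emission(m, 2)
  bf <- bf_bin_means(g$emission, as.numeric(1:20), valid[1, ], 2)
  expect_equal(dn$intensities[1, ], bf$means, tolerance = 1e-12)
  expect_equal(dn$valid[1, ], !is.na(bf$means))
})

test_that("referencing subtracts the first spectrum per pixel", {
  g <- toy_grid()
  a <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  b <- matrix(c(2, 1, 5, 3, 10, 0), 2, 3)
  s <- spectrum_series("A1", "c", list(
    eem_measurement("A1", 0, a, g), eem_measurement("A1", 1, b, g)))
  r <- reference_to_initial(s)
  expect_equal(r$measurements[[1]]$intensities, a - a)
  expect_equal(r$measurements[[2]]$intensities, b - a)  # hand subtraction
  # re-referencing changes later spectra relative to single referencing
  r2 <- reference_to_initial(r)
  expect_equal(r2$measurements[[2]]$intensities, b - a)  # first is now zero
  # inconsistent masks abort
  s$measurements[[2]] <- mask_scatter(s$measurements[[2]], c(-60, 60))
  expect_error(reference_to_initial(s), "inconsistent masks")
})

test_that("unfolding is excitation-major and invertible on valid pixels", {
  g <- toy_grid()
  vals <- matrix(c(11, 21, 12, 22, 13, 23), 2, 3)  # [i,j] = 10*i + j
  m <- eem_measurement("A1", 0, vals, g)
  uf <- unfold_to_features(m)
  expect_equal(uf$values, c(11, 12, 13, 21, 22, 23))
  expect_equal(uf$index$ex_nm, rep(c(300, 400), each = 3))
  expect_equal(uf$index$em_nm, rep(c(350, 355, 360), 2))
  # with a mask, length equals brute-force count and refold inverts
  mm <- mask_scatter(rand_measurement(grid_mid()), c(-10, 13))
  uf2 <- unfold_to_features(mm)
  expect_equal(length(uf2$values),
               prod(dim_eem(mm$grid)) - bf_band_count(mm$grid, -10, 13))
  back <- refold_features(uf2$values, uf2$index, mm$grid)
  expect_equal(back[mm$valid], mm$intensities[mm$valid])
  expect_true(all(is.na(back[!mm$valid])))
  mall <- mask_scatter(rand_measurement(toy_grid()), c(-1000, 1000))
  expect_error(unfold_to_features(mall), "no valid pixels")
})

test_that("the chain applies steps in order and matches manual application", {
  g <- grid_mid()
  m <- rand_measurement(g, seed = 11)
  s <- spectrum_series("A1", "c", list(
    m, eem_measurement("A1", 1, m$intensities * 1.3, g)))
  cfg <- preprocess_config(em_window_rel = c(-10, 270), smooth_window_px = 5,
                           target_em_step = 8, include_scatter = FALSE,
                           reference_to_t0 = TRUE)
  out <- preprocess_series(s, cfg)
  manual <- lapply(s$measurements, function(mi) {
    mi <- restrict_emission_window(mi, c(-10, 270))
    mi <- smooth_emission(mi, 5)
    mi <- downsample_emission(mi, 8)
    mask_scatter(mi, c(-10, 13))
  })
  i0 <- manual[[1]]$intensities
  expect_equal(out$measurements[[1]]$intensities, i0 - i0)
  expect_equal(out$measurements[[2]]$intensities,
               manual[[2]]$intensities - i0, tolerance = 1e-12)
  # all steps disabled: identity
  cfg0 <- preprocess_config(em_window_rel = NULL, smooth_window_px = 1,
                            target_em_step = NULL, include_scatter = TRUE,
                            reference_to_t0 = FALSE)
  expect_identical(preprocess_series(s, cfg0), s)
})

test_that("default fluorescence-only chain keeps, at ex 420, em in (433, 690]", {
  g <- default_grid("caption")
  m <- eem_measurement("A1", 0, matrix(1, 43, 983), g)
  s <- spectrum_series("A1", "c", list(m))
  out <- preprocess_series(s, preprocess_config(include_scatter = FALSE,
                                                reference_to_t0 = FALSE))
  mm <- out$measurements[[1]]
  i <- which(mm$grid$excitation == 420)
  kept <- mm$grid$emission[mm$valid[i, ]]
  expect_true(all(kept > 433 & kept <= 690))
  expect_equal(kept, seq(434, 690, by = 2))
})

test_that("smoothing and downsampling do not commute on random input", {
  g <- grid_mid()
  m <- rand_measurement(g, seed = 21)
  a <- downsample_emission(smooth_emission(m, 5), 8)
  b <- smooth_emission(downsample_emission(m, 8), 5)
  expect_gt(max(abs(a$intensities - b$intensities)), 1e-6)
})

test_that("masks only grow along the chain and wells never interact", {
  g <- grid_mid()
  m <- rand_measurement(g, seed = 31)
  steps <- list(
    function(x) restrict_emission_window(x, c(-10, 270)),
    function(x) smooth_emission(x, 5),
    function(x) downsample_emission(x, 8),
    function(x) mask_scatter(x, c(-10, 13)))
  cur <- m
  for (f in steps) {
    nxt <- f(cur)
    if (identical(dim(nxt$valid), dim(cur$valid))) {
      # no pixel masked earlier may become valid again
      expect_false(any(nxt$valid & !cur$valid))
    } else {
      # downsampling: output valid only where some contributor was valid
      expect_gte(mean(!nxt$valid), 0)
    }
    cur <- nxt
  }
  # per-well locality: a well's output is unchanged by other wells' order
  s1 <- spectrum_series("A1", "c", list(rand_measurement(g, 41),
                                        eem_measurement("A1", 1,
                                          rand_measurement(g, 42)$intensities, g)))
  cfg <- preprocess_config(smooth_window_px = 5, target_em_step = 8)
  alone <- preprocess_series(s1, cfg)
  with_others <- lapply(list(s1), preprocess_series, cfg = cfg)[[1]]
  expect_identical(alone, with_others)
})

test_that("fluorescence-only output equals the scatter-included output on shared pixels", {
  g <- grid_mid()
  m <- rand_measurement(g, seed = 51)
  s <- spectrum_series("A1", "c", list(
    m, eem_measurement("A1", 1, m$intensities * 2, g)))
  keep <- preprocess_series(s, preprocess_config(smooth_window_px = 5,
                                                 target_em_step = 8))
  drop <- preprocess_series(s, preprocess_config(smooth_window_px = 5,
                                                 target_em_step = 8,
                                                 include_scatter = FALSE))
  for (k in 1:2) {
    shared <- drop$measurements[[k]]$valid
    expect_true(all(keep$measurements[[k]]$valid[shared]))
    expect_equal(drop$measurements[[k]]$intensities[shared],
                 keep$measurements[[k]]$intensities[shared])
  }
})
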