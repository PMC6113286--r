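test_that("filter components evaluate to their closed forms", {
  flt <- motion_filters()
  cx <- (nrow(flt$f1) + 1) / 2
  cy <- (ncol(flt$f1) + 1) / 2
  expect_equal(flt$f1[cx, cy], 1)           # cos^4(0) cos(0) exp(0)
  expect_equal(max(abs(flt$f2[cx, ])), 0)   # odd filter vanishes at x = 0
  expect_equal(flt$g1[1], 0)                # g(0) = 0
  expect_gt(min(flt$g1[2:4]), 0)

  # temporal peak position agrees with direct 1-D maximisation
  gfun <- function(t) (60 * t)^3 * exp(-60 * t) *
    (1 / factorial(3) - (60 * t)^2 / factorial(5))
  t_peak <- optimize(gfun, c(0, 0.15), maximum = TRUE)$maximum
  expect_lt(abs(flt$t[which.max(flt$g1)] - t_peak), 1 / 75)

  # even/odd symmetry about the filter axis
  expect_equal(flt$f1, flt$f1[rev(seq_len(nrow(flt$f1))), ])
  expect_equal(flt$f2, -flt$f2[rev(seq_len(nrow(flt$f2))), ])
})

test_that("dot movies have the stated geometry and density", {
  m <- dot_movie(0.5, 30, aperture_deg = 5, seed = 71)
  expect_equal(dim(m$frames)[3], 30L)
  counts <- apply(m$frames, 3, sum)
  # dots per frame = density * area / frame rate, within rounding and pixel
  # collisions
  expect_equal(round(16.7 * pi * 2.5^2 / 75), 4)
  expect_true(all(counts <= 4) && mean(counts) > 3.5)
  expect_error(dot_movie(1.5, 10), "coherence")
  expect_error(dot_movie(1, 10, aperture_deg = 0.1), "displacement")
  expect_identical(dot_movie(0.3, 20, seed = 5)$frames,
                   dot_movie(0.3, 20, seed = 5)$frames)
})

test_that("net energy is zero for blank input and antisymmetric under mirroring", {
  flt <- motion_filters()
  blank <- dot_movie(0, 40, aperture_deg = 3, seed = 72)
  blank$frames[] <- 0
  expect_true(all(net_motion_energy(blank, flt) == 0))

  m <- dot_movie(1, 40, aperture_deg = 3, seed = 73)
  e <- net_motion_energy(m, flt)
  mf <- m
  mf$frames <- m$frames[rev(seq_len(dim(m$frames)[1])), , ]
  ef <- net_motion_energy(mf, flt)
  expect_equal(as.numeric(ef), -as.numeric(e), tolerance = 1e-10)
  # the per-direction energies swap under the mirror
  expect_equal(attr(ef, "per_direction")[, "right"],
               attr(e, "per_direction")[, "left"], tolerance = 1e-10)

  # per-direction energies are non-negative before opponent subtraction
  pd <- attr(e, "per_direction")
  expect_true(all(pd >= 0))
})

test_that("energy is direction selective along the filter axis", {
  flt <- motion_filters()
  m <- dot_movie(1, 40, aperture_deg = 3, seed = 74)
  e_pref <- mean(net_motion_energy(m, flt)[15:40])
  # rotating the movie 90 degrees moves the motion off the filter axis
  mo <- m
  mo$frames <- aperm(m$frames, c(2, 1, 3))
  e_orth <- mean(net_motion_energy(mo, flt)[15:40])
  expect_gt(e_pref, 0)
  expect_gt(e_pref, 3 * abs(e_orth))
  # leftward motion gives negative net energy
  ml <- dot_movie(1, 40, aperture_deg = 3, direction = -1, seed = 75)
  expect_lt(mean(net_motion_energy(ml, flt)[15:40]), 0)
})

test_that("the calibration slope is linear and scale-covariant", {
  sl <- coherence_energy_slope(c(0, 0.25, 0.5), c(0, 1, 2))
  expect_equal(sl$slope, 4)
  expect_equal(sl$r_squared, 1)
  sl2 <- coherence_energy_slope(c(0, 0.25, 0.5), 2 * c(0, 1, 2))
  expect_equal(sl2$slope, 8)
  expect_error(coherence_energy_slope(c(0.5, 0.5), c(1, 1)), "levels")

  expect_equal(energy_to_coherence(1, 2), 0.5)
  expect_equal(energy_to_coherence(0, 2), 0)
  expect_error(energy_to_coherence(1, -1), "positive")
})

test_that("step-lag measurement locates a known half-rise", {
  resp <- c(rep(0, 20), 0.2, 0.6, 0.9, rep(1, 17))
  lag <- energy_step_lag(resp, step_frame = 20, settle_frames = 5)
  expect_gt(lag, 1); expect_lt(lag, 3)
  expect_error(energy_step_lag(resp, 45), "beyond")
})
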