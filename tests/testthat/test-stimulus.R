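test_that("gaussian stimulus reproduces requested moments", {
  # zero-noise degenerate case: every entry equals the trial mean
  s0 <- gaussian_stimulus(1000, 5, sigma_s = 0, trial_means = 0.1, seed = 1)
  expect_true(all(s0$values == 0.1))

  # law of large numbers on the grand mean and a chi-square band on the
  # per-frame sd
  s <- gaussian_stimulus(1e4, 75, sigma_s = 1, seed = 2)
  expect_lt(abs(mean(s$values)), 4 / sqrt(length(s$values)))
  frame_sds <- apply(s$values[, c(1, 40, 75)], 2, sd)
  expect_true(all(frame_sds > 0.97 & frame_sds < 1.03))

  # per-trial means are honoured
  sm <- gaussian_stimulus(500, 200, sigma_s = 1,
                          trial_means = seq(-0.5, 0.5, length.out = 500),
                          seed = 3)
  expect_lt(max(abs(rowMeans(sm$values) - sm$trial_mean)), 4 / sqrt(200))
})

test_that("stimulus generation is bit-reproducible under a fixed seed", {
  a <- gaussian_stimulus(50, 20, sigma_s = 1, seed = 42)
  b <- gaussian_stimulus(50, 20, sigma_s = 1, seed = 42)
  expect_identical(a$values, b$values)
  f1 <- face_features(20, 10, sd = 20, seed = 42)
  f2 <- face_features(20, 10, sd = 20, seed = 42)
  expect_identical(f1$values, f2$values)
})

test_that("stimulus parameter validation rejects bad inputs", {
  expect_error(gaussian_stimulus(0, 10), "n_trials")
  expect_error(gaussian_stimulus(10, 10, sigma_s = -1), "sigma_s")
  expect_error(gaussian_stimulus(10, 10, trial_means = c(1, 2)), "trial_means")
})

test_that("weight functions evaluate to their closed forms", {
  expect_equal(evaluate_weights(weight_spec("polynomial", gamma = 1), 0.5), 1)
  expect_equal(
    evaluate_weights(weight_spec("polynomial", gamma = 2, beta1 = 1,
                                 beta2 = -1), 1), 2)
  expect_equal(
    evaluate_weights(weight_spec("sinusoid", gamma = 1, amplitude = 0.5,
                                 period = 1), 0.25), 1.5)
  w <- weight_spec("constant", gamma = 3)
  expect_equal(evaluate_weights(w, c(0, 1, 7)), rep(3, 3))
  expect_error(evaluate_weights(w, -1), "non-negative")
  expect_error(weight_spec("wiggle"), "arg")
})

test_that("face features respect range, sd, and independence", {
  ff <- face_features(600, 12, sd = 20, seed = 7)
  expect_true(all(abs(ff$values) <= 100))
  # per-feature fluctuation sd approaches the nominal 20% morph
  dev <- sweep(ff$values, 1, ff$mean_morph)
  expect_lt(abs(sd(dev) - 20) / 20, 0.05)
  # features mutually independent given the trial mean
  cors <- cor(cbind(dev[, , 1][, 1], dev[, , 2][, 1], dev[, , 3][, 1]))
  expect_lt(max(abs(cors[upper.tri(cors)])), 4 / sqrt(600))

  # zero-noise: values exactly the mean, nothing rejected
  f0 <- face_features(10, 4, mean_morphs = 30, sd = 0, seed = 8)
  expect_true(all(f0$values == 30))
  expect_equal(f0$rejected_fraction, 0)
  expect_error(face_features(10, 4, mean_morphs = 130), "range")
})

test_that("rejection resampling matches truncated-normal predictions", {
  # near the range edge, resampling pulls the mean below the nominal mean
  fe <- face_features(2000, 10, mean_morphs = 99, sd = 20, seed = 9)
  emp <- mean(fe$values)
  oracle <- truncnorm_mean(99, 20, -100, 100)
  expect_lt(emp, 99)
  expect_lt(abs(emp - oracle), 4 * 20 / sqrt(length(fe$values)))

  # analytic rejection probability: direct CDF arithmetic, and the value
  # quoted for the seven-level design
  p <- face_rejection_rate(means = 50, sd = 20)
  expect_equal(p, pnorm(-100, 50, 20) + pnorm(100, 50, 20, lower.tail = FALSE))
  expect_equal(round(100 * face_rejection_rate(), 2), 0.18)
})
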