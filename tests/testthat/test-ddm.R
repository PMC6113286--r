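test_that("bound profile follows the hyperbolic collapse", {
  u <- urgency_spec(b = 60, u_inf = 60, tau_half = 0.4)
  expect_equal(bound_profile(0, u), 60)
  expect_equal(bound_profile(0.4, u), 30)   # half the reduction at tau_half
  expect_lt(bound_profile(1e6, u), 1e-3)    # asymptote b - u_inf = 0
  prof <- bound_profile(seq(0, 5, 0.1), u)
  expect_true(all(diff(prof) <= 0))
  expect_error(bound_profile(-1, u), "non-negative")
  expect_error(urgency_spec(60, 70, 0.4), "u_inf")
})

test_that("analytic bound-crossing probability is (B + dv) / 2B", {
  expect_equal(bound_crossing_prob(0, 30), 0.5)
  expect_equal(bound_crossing_prob(30, 30), 1)
  expect_equal(bound_crossing_prob(-30, 30), 0)
  expect_equal(bound_crossing_prob(15, 30), 0.75)
  expect_error(bound_crossing_prob(31, 30), "bound")
})

test_that("noise-free ramp crosses deterministically at the predicted frame", {
  m <- 0.5; B <- 10; n_frames <- 60
  stim <- hand_stimulus(matrix(m, 3, n_frames))
  tr <- simulate_ddm(ddm_spec(bound = B, sigma_eta = 0), stim, task = "rt")
  expect_true(all(tr$choice == 1L))
  expect_true(all(tr$crossed))
  expect_equal(tr$decision_time, rep(ceiling(B / m) / 75, 3))
  # negative ramp hits the lower bound
  tr2 <- simulate_ddm(ddm_spec(bound = B, sigma_eta = 0),
                      hand_stimulus(matrix(-m, 3, n_frames)), task = "rt")
  expect_true(all(tr2$choice == 2L))
})

test_that("mean-zero unbiased simulation splits choices evenly", {
  stim <- gaussian_stimulus(4e4, 400, sigma_s = 1, seed = 11)
  tr <- suppressMessages(
    simulate_ddm(ddm_spec(bound = 15, sigma_eta = 1), stim, seed = 12))
  p1 <- mean(tr$choice[tr$crossed] == 1L)
  expect_lt(abs(p1 - 0.5), 4 * sqrt(0.25 / sum(tr$crossed)))
  expect_true(all(tr$rt >= tr$decision_time - 1e-12, na.rm = TRUE))
})

test_that("interior restarts absorb with the analytic probability", {
  # the frame-based walk has a documented O(frame) overshoot bias: the
  # effective bound is inflated by about 0.58 * per-frame evidence sd, so the
  # empirical frequency must sit between the analytic value and the
  # overshoot-corrected one (within MC error)
  stim <- gaussian_stimulus(2e4, 1500, sigma_s = 1, seed = 13)
  B <- 30
  for (x in c(-15, 15)) {
    tr <- suppressMessages(
      simulate_ddm(ddm_spec(bound = B, sigma_eta = 1, start_point = x),
                   stim, seed = 14 + x))
    p <- mean(tr$choice[tr$crossed] == 1L)
    p_exact <- bound_crossing_prob(x, B)
    p_over <- bound_crossing_prob(x, B + 0.6 * sqrt(2))
    se <- sqrt(0.25 / sum(tr$crossed))
    expect_lt(min(abs(p - p_exact), abs(p - p_over)), 4 * se)
    expect_lt(abs(p - p_exact), abs(p_exact - 0.5) * 0.1 + 4 * se)
  }
})

test_that("non-decision-time sampler matches its nominal moments", {
  expect_equal(sample_ndt(ndt_spec(0.3, 0), 5), rep(0.3, 5))
  x <- sample_ndt(ndt_spec(0.3, 0.1), 1e5, seed = 15)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 0.3), 0.003)   # truncation negligible at 3 sigma
  g <- sample_ndt(ndt_spec(0.3, 0.1, family = "gamma"), 2e5, seed = 16)
  expect_lt(abs(mean(g) - 0.3), 0.003)
  skew <- mean(((g - mean(g)) / sd(g))^3)
  expect_lt(abs(skew - 2 * 0.1 / 0.3), 0.06)  # gamma skewness = 2 sd/mean
  expect_error(ndt_spec(0.3, -0.1), "sd_T0")
})

test_that("unbounded integration chooses by terminal-DV sign with the right variance", {
  s1 <- hand_stimulus(matrix(3, 1, 1))
  tr <- simulate_unbounded_ddm(ddm_spec(sigma_eta = 0), s1)
  expect_equal(tr$choice, 1L)
  expect_equal(tr$terminal_dv, 3)

  stim <- gaussian_stimulus(5e4, 75, sigma_s = 1, seed = 17)
  tru <- simulate_unbounded_ddm(ddm_spec(sigma_eta = 1), stim, seed = 18)
  st2 <- sigma_tot(75, 1 / 75, 1, 1, weight_spec("constant"))^2
  expect_equal(st2, 150)   # discrete variance sum: 75 * 1 + 1 * 75
  expect_lt(abs(var(tru$terminal_dv) / st2 - 1), 0.05)
  expect_identical(tru$choice, ifelse(tru$terminal_dv > 0, 1L, 2L))
})

test_that("doubling the bound halves the raw kernel amplitude", {
  stim <- gaussian_stimulus(4e4, 700, sigma_s = 1, seed = 19)
  t1 <- suppressMessages(
    simulate_ddm(ddm_spec(bound = 15, sigma_eta = 1), stim, seed = 20))
  t2 <- suppressMessages(
    simulate_ddm(ddm_spec(bound = 30, sigma_eta = 1), stim, seed = 21))
  k1 <- psych_kernel(stim, t1)
  k2 <- psych_kernel(stim, t2)
  m1 <- mean(k1$value, na.rm = TRUE)
  m2 <- mean(k2$value, na.rm = TRUE)
  expect_equal(m1, 2 / 15, tolerance = 0.08)
  expect_equal(m2 / m1, 0.5, tolerance = 0.1)
})

test_that("internal noise leaves the RT-task kernel unchanged", {
  stim <- gaussian_stimulus(4e4, 700, sigma_s = 1, seed = 22)
  t0 <- suppressMessages(
    simulate_ddm(ddm_spec(bound = 15, sigma_eta = 0), stim, seed = 23))
  t1 <- suppressMessages(
    simulate_ddm(ddm_spec(bound = 15, sigma_eta = 1), stim, seed = 24))
  k0 <- psych_kernel(stim, t0)
  k1 <- psych_kernel(stim, t1)
  nb <- min(nrow(k0), nrow(k1))
  z <- (mean(k0$value[1:nb], na.rm = TRUE) - mean(k1$value[1:nb], na.rm = TRUE)) /
    sqrt(mean(k0$sem[1:nb]^2 + k1$sem[1:nb]^2, na.rm = TRUE) / nb)
  expect_lt(abs(z), 4)
})

test_that("simulation seeds give identical trial tables", {
  stim <- gaussian_stimulus(200, 300, sigma_s = 1, seed = 25)
  spec <- ddm_spec(bound = 10, sigma_eta = 1, ndt = ndt_spec(0.3, 0.1))
  a <- simulate_ddm(spec, stim, seed = 26)
  b <- simulate_ddm(spec, stim, seed = 26)
  expect_identical(a, b)
})
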