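test_that("the kernel reproduces hand-computed conditional means", {
  # 4 trials, frame 0: choice-1 stimuli {+1, +3}, choice-2 stimuli {-1, +1}
  values <- matrix(c(1, 3, -1, 1,
                     0, 0, 0, 0), 4, 2)
  stim <- hand_stimulus(values)
  tr <- hand_trials(choice = c(1, 1, 2, 2), rt = rep(10 / 75, 4))
  k <- suppressWarnings(psych_kernel(stim, tr, window = 2 / 75))
  expect_equal(k$value[1], 2)          # (1+3)/2 - (-1+1)/2
  expect_equal(k$n[1], 4L)

  # a choice-2 trial whose RT precedes bin 2 is excluded from that bin,
  # which then has one choice-2 trial left and goes missing
  tr2 <- hand_trials(choice = c(1, 1, 2, 2), rt = c(10, 10, 10, 0.5) / 75)
  k2 <- suppressWarnings(psych_kernel(stim, tr2, window = 2 / 75))
  expect_equal(k2$n[1], 4L)
  expect_equal(k2$n[2], 3L)
  expect_true(is.na(k2$value[2]))
  expect_false(is.na(k2$value[1]))

  # all-one-choice input is an error; thin bins go missing with a warning
  tr3 <- hand_trials(choice = c(1, 1, 1, 1), rt = rep(1, 4))
  expect_error(psych_kernel(stim, tr3), "both choice")
  expect_warning(psych_kernel(stim, tr2, window = 2 / 75), "fewer than 2")
})

test_that("choice-shuffled stimuli give a null kernel and label swaps negate it", {
  stim <- gaussian_stimulus(4000, 50, sigma_s = 1, seed = 41)
  set.seed(42)
  tr <- hand_trials(choice = sample(c(1L, 2L), 4000, TRUE),
                    rt = rep(50 / 75, 4000))
  k <- psych_kernel(stim, tr, window = 40 / 75)
  expect_true(all(abs(k$value) < 4 * k$sem))

  swapped <- tr
  swapped$choice <- 3L - tr$choice
  ks <- psych_kernel(stim, swapped, window = 40 / 75)
  expect_equal(ks$value, -k$value)
})

test_that("normalization inverts the analytic kernel-weight scale factors", {
  # bounded: a kernel equal to (2 sigma_s^2 / B) w recovers w exactly
  w <- c(1, 1.2, 0.8, 1)
  kern <- structure(
    data.frame(time = (0:3) / 75, value = 2 / 30 * w, sem = 0.01, n = 100L),
    alignment = "stimulus", normalization = "raw", frame_dt = 1 / 75,
    window_end = 4 / 75, median_rt = 0.5, scale_value = 1,
    class = c("psych_kernel", "data.frame"))
  kn <- normalize_kernel(kern, "bounded", sigma_s = 1, bound = 30)
  expect_equal(kn$value, w)

  # collapsing bound: the scale uses the profile averaged over [0, median RT]
  u <- urgency_spec(60, 60, 0.4)
  ku <- normalize_kernel(kern, "bounded", sigma_s = 1, urgency = u,
                         median_rt = 0.4)
  b_avg <- integrate(function(t) bound_profile(t, u), 0, 0.4)$value / 0.4
  expect_equal(attr(ku, "scale_value"), 2 / b_avg, tolerance = 1e-6)

  # unbounded scale and its sigma_tot
  st <- sigma_tot(75, 1 / 75, 1, 1)
  expect_equal(st^2, 150)
  kU <- normalize_kernel(kern, "unbounded", sigma_s = 1, sigma_tot = st)
  expect_equal(attr(kU, "scale_value"), 4 / (sqrt(2 * pi) * st))
  expect_error(normalize_kernel(kern, "unbounded"), "sigma_tot")
  expect_error(normalize_kernel(kern, "bounded"), "bound")
})

test_that("distortion is the RMSE against the weight function", {
  kern <- structure(
    data.frame(time = (0:9) / 75, value = rep(1.5, 10), sem = 0, n = 10L),
    alignment = "stimulus", normalization = "bounded", frame_dt = 1 / 75,
    window_end = 10 / 75, median_rt = 1, scale_value = 1,
    class = c("psych_kernel", "data.frame"))
  expect_equal(kernel_distortion(kern, rep(1.5, 10)), 0)
  expect_equal(kernel_distortion(kern, weight_spec("constant")), 0.5)
  set.seed(43)
  w <- rnorm(10)
  expect_equal(kernel_distortion(kern, w),
               sqrt(mean((w - kern$value)^2)))   # brute-force recomputation
  expect_error(kernel_distortion(kern, 1:3), "grids")
})

test_that("averaging kernels truncates to the shortest window", {
  mk <- function(values, window) {
    structure(data.frame(time = (seq_along(values) - 1) / 75, value = values,
                         sem = 0.1, n = 50L),
              alignment = "stimulus", normalization = "raw", frame_dt = 1 / 75,
              window_end = window, median_rt = window, scale_value = 1,
              class = c("psych_kernel", "data.frame"))
  }
  a <- mk(rep(0, 60), 0.8)
  b <- mk(rep(2, 45), 0.6)
  avg <- average_kernels(list(a, b))
  expect_equal(nrow(avg), 45L)
  expect_true(all(avg$value == 1))
  expect_equal(attr(avg, "window_end"), 0.6)
  same <- average_kernels(list(a, a))
  expect_equal(same$value, a$value[1:60])
  expect_true(all(same$sem == 0))
  resp <- mk(rep(1, 45), 0.6)
  attr(resp, "alignment") <- "response"
  expect_error(average_kernels(list(a, resp)), "alignments")
})

test_that("response-aligned kernels drop trials that outran the stimulus", {
  stim <- gaussian_stimulus(400, 30, sigma_s = 1, seed = 44)
  rt <- c(rep(20 / 75, 200), rep(45 / 75, 200))  # half beyond the 30 frames
  set.seed(45)
  tr <- hand_trials(choice = sample(c(1L, 2L), 400, TRUE), rt = rt)
  k <- suppressWarnings(psych_kernel(stim, tr, align = "response",
                                     window = 10 / 75))
  expect_equal(max(k$n), 200L)
  expect_true(all(k$time < 0))
})

test_that("trimming the non-decision time from RTs restores the flat kernel", {
  # with a FIXED non-decision time T0, the frames in the last T0 before each
  # response never influence the choice and dilute the kernel; conditioning
  # on rt - T0 (the true decision times) removes every contaminated frame
  # and recovers the flat bounded-DDM kernel at 2 sigma_s^2 / B
  stim <- gaussian_stimulus(3e4, 200, sigma_s = 1, seed = 46)
  spec <- ddm_spec(bound = 10, sigma_eta = 1, ndt = ndt_spec(0.2, 0))
  tr <- suppressMessages(simulate_ddm(spec, stim, seed = 47))
  k_raw <- psych_kernel(stim, tr)
  trimmed <- tr
  trimmed$rt <- tr$rt - 0.2
  k_trim <- psych_kernel(stim, trimmed)
  m_trim <- mean(k_trim$value, na.rm = TRUE)
  # the discrete walk overshoots the bound by ~0.58 * per-frame evidence sd,
  # so the kernel scale sits between 2/(B + overshoot) and 2/B
  expect_gt(m_trim, 0.95 * 2 / (10 + 0.6 * sqrt(2)))
  expect_lt(m_trim, 1.05 * 2 / 10)
  # the trimmed kernel has no trend; the untrimmed one is diluted below it
  trend <- suppressWarnings(cor.test(k_trim$time, k_trim$value,
                                     method = "spearman"))
  expect_gt(trend$p.value, 0.01)
  expect_lt(mean(k_raw$value, na.rm = TRUE), m_trim)
})
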