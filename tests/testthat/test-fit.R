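# Fast machinery checks for the ML fitter; full-scale parameter recovery at
# the task's data scale lives in the acceptance suite.

make_ddm_data <- function(n_per, gamma = 15, bound = 1.2, seed = 61,
                          cohs = c(0, 0.128, 0.512)) {
  set.seed(seed)
  do.call(rbind, lapply(cohs, function(cc) {
    d <- simulate_diffusion(n_per, gamma * cc, bound, t_max = 8, dt = 1e-3)
    ok <- !is.na(d$choice)
    data.frame(condition = cc, choice = d$choice[ok],
               rt = d$decision_time[ok] +
                 sample_ndt(ndt_spec(0.3, 0.1), sum(ok)))
  }))
}

test_that("a reduced fit lands near the generating parameters", {
  gen <- make_ddm_data(250)
  fit <- ddm_fit(gen, "coherence", n_restarts = 2, dt = 2e-3, seed = 62)
  expect_s3_class(fit, "ddm_fit")
  cf <- coef(fit)
  expect_equal(unname(cf["bound"]), 1.2, tolerance = 0.15)
  expect_equal(unname(cf["gamma"]), 15, tolerance = 0.2)
  expect_equal(unname(cf["mean_T0"]), 0.3, tolerance = 0.15)
  expect_true(is.finite(logLik(fit)))
  expect_equal(attr(logLik(fit), "nobs"), fit$n)
  expect_true(!is.null(fit$se))
  expect_equal(dim(vcov(fit)), c(4L, 4L))
  # summary and print run without error
  expect_output(print(summary(fit)), "Drift-diffusion fit")
})

test_that("the log-likelihood evaluator agrees with the fitted optimum", {
  gen <- make_ddm_data(150, seed = 63)
  fit <- ddm_fit(gen, "coherence", n_restarts = 1, dt = 2e-3, seed = 64)
  ll <- ddm_loglik(gen, coef(fit), "coherence", dt = 2e-3)
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
  # perturbing a parameter reduces the likelihood at the optimum
  worse <- coef(fit)
  worse["bound"] <- worse["bound"] * 1.3
  expect_lt(ddm_loglik(gen, worse, "coherence", dt = 2e-3), ll)
  # nesting: a zero-beta time-varying drift reproduces the static likelihood
  ll_tv <- ddm_loglik(gen, c(coef(fit), beta1 = 0, beta2 = 0),
                      "time_varying", dt = 2e-3)
  expect_equal(ll_tv, ll, tolerance = 1e-8)
})

test_that("forward simulation from a fit produces valid trial tables", {
  fit <- structure(
    list(coefficients = c(bound = 1.2, gamma = 15, mean_T0 = 0.3,
                          sd_T0 = 0.1),
         drift = "coherence", conditions = c(0, 0.256), n = 100,
         logLik = 0, dt = 1e-3, nv = 513),
    class = "ddm_fit")
  sim <- simulate(fit, nsim = 300, seed = 65)
  expect_true(all(sim$choice %in% c(1L, 2L)))
  expect_true(all(sim$rt > 0))
  expect_gt(mean(sim$choice[sim$condition == 0.256] == 1L), 0.85)
  expect_lt(abs(mean(sim$choice[sim$condition == 0] == 1L) - 0.5), 0.15)
  # reproducible under the same seed
  expect_identical(sim, simulate(fit, nsim = 300, seed = 65))
})

test_that("kernel prediction forwards fitted parameters into the simulator", {
  fit <- structure(
    list(coefficients = c(bound = 1.2, gamma = 15, mean_T0 = 0.3,
                          sd_T0 = 0.1),
         drift = "coherence", conditions = c(0, 0.256), n = 100,
         logLik = 0, dt = 1e-3, nv = 513),
    class = "ddm_fit")
  stim <- gaussian_stimulus(5e3, 150, frame_dt = 1 / 75, sigma_s = 0.2,
                            seed = 66)
  pred <- suppressMessages(predict(fit, stim, seed = 67))
  expect_s3_class(pred$kernel, "psych_kernel")
  expect_gt(mean(pred$kernel$value, na.rm = TRUE), 0)   # positive weights
  expect_gt(pred$median_rt, 0.3)                        # NDT floor
})

test_that("multi-feature drift fits and predicts from per-trial streams", {
  # machinery check at a deliberately tiny scale: generate choices/RTs from
  # a three-feature drift, fit with per-trial Fokker-Planck solves, and
  # predict feature kernels
  ff <- face_features(60, 16, mean_morphs = c(-30, 0, 30), sd = 20,
                      seed = 68)
  ff$values <- ff$values / 100    # work in fractions
  ff$sd <- ff$sd / 100
  gam <- c(6, 4, 2)
  fdt <- ff$frame_dt
  drive <- (gam[1] * ff$values[, , 1] + gam[2] * ff$values[, , 2] +
              gam[3] * ff$values[, , 3]) * fdt
  stim_drive <- hand_stimulus(drive, frame_dt = fdt)
  stim_drive$sigma_s <- 0
  spec <- ddm_spec(bound = 1, sigma_eta = sqrt(fdt),
                   weight = weight_spec("constant", gamma = 1),
                   ndt = ndt_spec(0.25, 0.05))
  tr <- suppressMessages(simulate_ddm(spec, stim_drive, seed = 69))
  tab <- data.frame(choice = tr$choice, rt = tr$rt)[tr$crossed, ]
  ffk <- ff
  ffk$values <- ff$values[tr$crossed, , , drop = FALSE]
  fit <- ddm_fit(tab, "multi_feature", stimulus = ffk, n_restarts = 2,
                 dt = 4e-3, nv = 129, hessian = FALSE, seed = 70,
                 control = list(maxit = 60))
  expect_s3_class(fit, "ddm_fit")
  expect_true(is.finite(fit$logLik))
  expect_true(all(coef(fit)[c("gamma_e", "gamma_n", "gamma_m")] > 0))

  pred <- suppressMessages(suppressWarnings(
    predict(fit, face_features(2000, 16, mean_morphs = 0, sd = 0.2,
                               range = c(-1, 1), seed = 71), seed = 72)))
  expect_s3_class(pred$kernel, "psych_kernel_set")
  expect_named(pred$kernel, c("eyes", "nose", "mouth"))
})

test_that("face-feature streams yield one kernel per feature", {
  ff <- face_features(800, 10, mean_morphs = 0, sd = 20, seed = 73)
  set.seed(74)
  tr <- hand_trials(sample(c(1L, 2L), 800, TRUE), rep(10 * 8 / 75, 800),
                    frame_dt = 8 / 75)
  ks <- psych_kernel(ff, tr, window = 8 * 8 / 75)
  expect_s3_class(ks, "psych_kernel_set")
  expect_named(ks, c("eyes", "nose", "mouth"))
  for (k in ks) expect_true(all(abs(k$value) < 4 * k$sem))
})

test_that("fitting rejects malformed inputs", {
  expect_error(ddm_fit(data.frame(choice = 1, rt = 1)), "condition")
  expect_error(ddm_fit(data.frame(choice = 3, rt = 1, condition = 0.1)),
               "1/2")
  expect_error(ddm_fit(data.frame(choice = 1, rt = -1, condition = 0.1)),
               "positive|1/2")
  expect_error(ddm_fit(data.frame(choice = c(1, 2), rt = c(1, 1),
                                  condition = c(0.1, 0.1))),
               "two distinct")
  expect_error(ddm_fit(data.frame(choice = 1, rt = 1), "multi_feature"),
               "face_feature_stream")
})
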