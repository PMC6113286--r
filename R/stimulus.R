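# Stochastic stimulus ensembles and sensory weight functions.
#
# Stimuli are piecewise-constant per display frame: one independent Gaussian
# draw per frame, matching discrete-frame psychophysical displays (random-dot
# coherence at 75 Hz, face-morph updates at 9.4 Hz). All times are seconds.

#' Generate a Gaussian per-frame stimulus ensemble
#'
#' Draws `n_trials x n_frames` independent Gaussian evidence values. Each trial
#' has its own mean strength (e.g. signed coherence) and every frame adds
#' zero-mean fluctuation with standard deviation `sigma_s`. The ensemble is
#' the raw material for all simulators and for reverse correlation.
#'
#' @param n_trials number of trials (rows).
#' @param n_frames number of stimulus frames per trial (columns).
#' @param frame_dt frame duration in seconds. Default 13.3 ms (75 Hz display).
#' @param sigma_s per-frame fluctuation standard deviation (dimensionless
#'   evidence units, e.g. proportion coherence). May be 0.
#' @param trial_means scalar or length-`n_trials` vector of per-trial mean
#'   stimulus strength.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return An object of class `stimulus_ensemble`: a list with `values`
#'   (matrix), `frame_dt`, `sigma_s`, `trial_mean`, `seed`.
#' @examples
#' stim <- gaussian_stimulus(100, 75, sigma_s = 1, seed = 1)
#' dim(stim$values)
#' @export
gaussian_stimulus <- function(n_trials, n_frames, frame_dt = 1 / 75,
                              sigma_s = 1, trial_means = 0, seed = NULL) {
  check_scalar(n_trials, "n_trials", lower = 1)
  check_scalar(n_frames, "n_frames", lower = 1)
  check_scalar(frame_dt, "frame_dt", lower = .Machine$double.eps)
  check_scalar(sigma_s, "sigma_s", lower = 0)
  n_trials <- as.integer(n_trials)
  n_frames <- as.integer(n_frames)
  if (length(trial_means) == 1L) trial_means <- rep(trial_means, n_trials)
  if (length(trial_means) != n_trials) {
    stop_invalid("'trial_means' must have length 1 or n_trials")
  }
  values <- with_seed(seed, {
    matrix(stats::rnorm(n_trials * n_frames, mean = 0, sd = sigma_s),
           n_trials, n_frames) + trial_means
  })
  structure(
    list(values = values, frame_dt = frame_dt, sigma_s = sigma_s,
         trial_mean = trial_means, seed = seed),
    class = "stimulus_ensemble")
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  cat(sprintf(
    "Stimulus ensemble: %d trials x %d frames (frame_dt = %.4g s, sigma_s = %.3g)\n",
    nrow(x$values), ncol(x$values), x$frame_dt, x$sigma_s))
  cat(sprintf("  trial means: %s\n",
              paste(format(unique(round(x$trial_mean, 6))[seq_len(min(8, length(unique(x$trial_mean))))]),
                    collapse = ", ")))
  invisible(x)
}

#' Specify a sensory weight function w(t)
#'
#' The weight function multiplies the momentary stimulus before integration.
#' Three families are supported: a constant weight, a polynomial modulation
#' `gamma * (1 + beta1 t + beta2 t^2)` (the form used for time-varying drift
#' rates), and an additive sinusoid `gamma + amplitude * sin(2 pi t / period +
#' phase)`.
#'
#' @param kind one of `"constant"`, `"polynomial"`, `"sinusoid"`.
#' @param gamma base sensitivity (weight at t = 0 for constant/polynomial).
#' @param beta1,beta2 linear and quadratic modulation coefficients
#'   (polynomial kind; units 1/s and 1/s^2).
#' @param amplitude,period,phase sinusoid parameters (same units as gamma,
#'   seconds, radians).
#' @return An object of class `weight_spec`.
#' @examples
#' evaluate_weights(weight_spec("polynomial", gamma = 2, beta1 = 1, beta2 = -1), 1)
#' @export
weight_spec <- function(kind = c("constant", "polynomial", "sinusoid"),
                        gamma = 1, beta1 = 0, beta2 = 0,
                        amplitude = 0, period = 1, phase = 0) {
  kind <- match.arg(kind)
  check_scalar(gamma, "gamma")
  check_scalar(beta1, "beta1"); check_scalar(beta2, "beta2")
  check_scalar(amplitude, "amplitude")
  check_scalar(period, "period", lower = .Machine$double.eps)
  check_scalar(phase, "phase")
  structure(list(kind = kind, gamma = gamma, beta1 = beta1, beta2 = beta2,
                 amplitude = amplitude, period = period, phase = phase),
            class = "weight_spec")
}

#' Evaluate a weight function at given times
#'
#' @param spec a [weight_spec()].
#' @param times vector of times in seconds (must be >= 0).
#' @return numeric vector of weights, one per time.
#' @export
evaluate_weights <- function(spec, times) {
  if (!inherits(spec, "weight_spec")) {
    stop_invalid("'spec' must be a weight_spec")
  }
  if (any(times < 0)) stop_invalid("'times' must be non-negative")
  switch(spec$kind,
    constant   = rep(spec$gamma, length(times)),
    polynomial = spec$gamma * (1 + spec$beta1 * times + spec$beta2 * times^2),
    sinusoid   = spec$gamma +
      spec$amplitude * sin(2 * pi * times / spec$period + spec$phase))
}

#' @export
print.weight_spec <- function(x, ...) {
  cat(sprintf("Weight function: %s (gamma = %.3g", x$kind, x$gamma))
  if (x$kind == "polynomial") cat(sprintf(", beta1 = %.3g, beta2 = %.3g", x$beta1, x$beta2))
  if (x$kind == "sinusoid") {
    cat(sprintf(", amplitude = %.3g, period = %.3g s, phase = %.3g", x$amplitude, x$period, x$phase))
  }
  cat(")\n")
  invisible(x)
}

#' Generate three-feature face-morph stimulus streams
#'
#' Emulates subliminal within-trial fluctuations of three facial features
#' (eyes, nose, mouth) expressed as % morph between two prototype faces. Each
#' frame's feature values are independent Gaussian draws around the trial's
#' mean morph; draws outside `range` are replaced by fresh draws
#' (rejection resampling, not clipping), and the fraction of initially
#' rejected draws is recorded.
#'
#' @param n_trials number of trials.
#' @param n_frames stimulus frames per trial.
#' @param mean_morphs per-trial mean morph level(s) in % morph. A scalar, a
#'   length-`n_trials` vector, or a set of condition levels to be assigned
#'   cyclically (default: the seven task levels -50 ... +50).
#' @param sd per-frame feature standard deviation in % morph (default 20).
#' @param frame_dt seconds per morph update; default 8 video frames at 75 Hz.
#' @param range allowed morph interval, default \code{c(-100, 100)}.
#' @param seed optional integer seed.
#' @return An object of class `face_feature_stream`: list with `values`
#'   (array `n_trials x n_frames x 3`), `feature_names`, `mean_morph`, `sd`,
#'   `frame_dt`, and `rejected_fraction` (share of first-pass draws that fell
#'   outside `range`).
#' @seealso [face_rejection_rate()] for the analytic rejection probability.
#' @export
face_features <- function(n_trials, n_frames,
                          mean_morphs = c(-50, -30, -14, 0, 14, 30, 50),
                          sd = 20, frame_dt = 8 / 75,
                          range = c(-100, 100), seed = NULL) {
  check_scalar(n_trials, "n_trials", lower = 1)
  check_scalar(n_frames, "n_frames", lower = 1)
  check_scalar(sd, "sd", lower = 0)
  check_scalar(frame_dt, "frame_dt", lower = .Machine$double.eps)
  n_trials <- as.integer(n_trials); n_frames <- as.integer(n_frames)
  if (any(abs(mean_morphs) > max(abs(range)))) {
    stop_invalid("mean morph levels must lie inside the allowed range")
  }
  means <- if (length(mean_morphs) == n_trials) mean_morphs else
    rep_len(mean_morphs, n_trials)
  n_feat <- 3L
  with_seed(seed, {
    total <- n_trials * n_frames * n_feat
    values <- stats::rnorm(total, mean = rep(means, n_frames * n_feat), sd = sd)
    bad <- which(values < range[1] | values > range[2])
    rejected <- length(bad)
    # resample until every value is inside the range
    while (length(bad) > 0L) {
      values[bad] <- stats::rnorm(length(bad),
                                  mean = rep(means, n_frames * n_feat)[bad],
                                  sd = sd)
      bad <- bad[values[bad] < range[1] | values[bad] > range[2]]
    }
    structure(
      list(values = array(values, dim = c(n_trials, n_frames, n_feat),
                          dimnames = list(NULL, NULL, c("eyes", "nose", "mouth"))),
           feature_names = c("eyes", "nose", "mouth"),
           mean_morph = means, sd = sd, frame_dt = frame_dt,
           rejected_fraction = rejected / total, seed = seed),
      class = "face_feature_stream")
  })
}

#' Analytic rejection probability for the face-feature sampler
#'
#' Probability that a first-pass Gaussian draw falls outside the allowed morph
#' range, averaged over the condition means with the given frequencies. With
#' the seven standard morph levels and sd = 20% this evaluates to ~0.18%.
#'
#' @param means condition mean morph levels (% morph).
#' @param sd per-frame standard deviation (% morph).
#' @param range allowed interval.
#' @param weights condition frequencies (default equal).
#' @return scalar probability.
#' @export
face_rejection_rate <- function(means = c(-50, -30, -14, 0, 14, 30, 50),
                                sd = 20, range = c(-100, 100),
                                weights = NULL) {
  check_scalar(sd, "sd", lower = 0)
  if (is.null(weights)) weights <- rep(1, length(means))
  weights <- weights / sum(weights)
  if (sd == 0) return(0)
  p <- stats::pnorm(range[1], means, sd) +
    stats::pnorm(range[2], means, sd, lower.tail = FALSE)
  sum(weights * p)
}

#' @export
print.face_feature_stream <- function(x, ...) {
  cat(sprintf(
    "Face feature stream: %d trials x %d frames x 3 features (sd = %.3g%% morph)\n",
    dim(x$values)[1], dim(x$values)[2], x$sd))
  cat(sprintf("  frame_dt = %.4g s; rejected first-pass draws: %.4g%%\n",
              x$frame_dt, 100 * x$rejected_fraction))
  invisible(x)
}
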