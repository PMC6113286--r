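# Two competing accumulators with input correlation, leak, mutual inhibition,
# a reflective lower bound, and absorbing upper bounds.
#
# Per-frame Euler update (frame duration is the natural time unit for leak and
# inhibition, which are quoted per frame):
#   dv = w(t) * S - L * v - I * v_swapped + v0 * (L + I) + dW
# with S = [s, -s] (the stimulus drives the accumulators in opposite
# directions) and dW a bivariate Gaussian with per-frame variance sigma_eta^2
# and correlation rho_prime. After each update both DVs are clamped at the
# reflective floor R (projection, the "firing rates cannot go negative"
# reading). The first accumulator to reach the absorbing bound sets the
# choice; simultaneous crossings are resolved by a fair coin flip.

#' Internal-noise correlation needed for a target input correlation
#'
#' The total momentary input to the two accumulators is w*s plus internal
#' noise; with opposite stimulus drive the input correlation is
#' \deqn{\rho = (-w^2 \sigma_s^2 + \rho' \sigma_\eta^2) /
#'              (w^2 \sigma_s^2 + \sigma_\eta^2).}
#' This solves for the internal-noise correlation `rho_prime` that achieves a
#' desired `rho_target`.
#'
#' @param rho_target desired input correlation, in [-1, 0].
#' @param w (constant) sensory weight.
#' @param sigma_s stimulus fluctuation sd per frame.
#' @param sigma_eta internal noise sd per frame.
#' @return `rho_prime`, or `NA` with attribute `stimulus_only = TRUE` when
#'   `sigma_eta = 0` (the correlation is then fixed at -1 by the stimulus).
#' @examples
#' race_noise_correlation(-0.2, 1, 1, 1)  # 0.6
#' @export
race_noise_correlation <- function(rho_target, w, sigma_s, sigma_eta) {
  check_scalar(rho_target, "rho_target", lower = -1, upper = 0)
  check_scalar(w, "w"); check_scalar(sigma_s, "sigma_s", lower = 0)
  check_scalar(sigma_eta, "sigma_eta", lower = 0)
  vs <- w^2 * sigma_s^2
  ve <- sigma_eta^2
  if (ve == 0) {
    if (abs(rho_target + 1) > 1e-12) {
      stop_invalid("with sigma_eta = 0 the input correlation is -1; ",
                   "rho_target = ", rho_target, " is infeasible")
    }
    return(structure(NA_real_, stimulus_only = TRUE))
  }
  rho_prime <- (rho_target * (vs + ve) + vs) / ve
  if (abs(rho_prime) > 1 + 1e-12) {
    lo <- (-vs - ve) / (vs + ve)
    hi <- (ve - vs) / (vs + ve)
    stop_invalid(sprintf(
      "rho_target = %.3g infeasible; feasible input correlations are [%.3g, %.3g]",
      rho_target, lo, min(0, hi)))
  }
  min(1, max(-1, rho_prime))
}

#' Competing-accumulator model specification
#'
#' @param rho target input correlation in [-1, 0]; the matching internal-noise
#'   correlation is derived via [race_noise_correlation()].
#' @param bound absorbing upper bound for each accumulator (> reflect).
#' @param reflect reflective lower bound R (may be `-Inf`).
#' @param leak leak rate L per frame (>= 0).
#' @param inhibition mutual inhibition I per frame (>= 0).
#' @param v0 common starting point of both DVs, in [reflect, bound).
#' @param sigma_eta per-frame internal noise sd (>= 0).
#' @param weight a [weight_spec()]; the input-correlation calculation uses its
#'   value at t = 0.
#' @param ndt optional [ndt_spec()].
#' @param urgency optional [urgency_spec()] (collapsing absorbing bound).
#' @return object of class `race_spec`.
#' @export
race_spec <- function(rho = -1, bound = 30, reflect = -Inf, leak = 0,
                      inhibition = 0, v0 = 0, sigma_eta = 1,
                      weight = weight_spec("constant"), ndt = NULL,
                      urgency = NULL) {
  check_scalar(rho, "rho", lower = -1, upper = 0)
  check_scalar(bound, "bound")
  check_scalar(reflect, "reflect", allow_inf = TRUE)
  check_scalar(leak, "leak", lower = 0)
  check_scalar(inhibition, "inhibition", lower = 0)
  check_scalar(v0, "v0")
  check_scalar(sigma_eta, "sigma_eta", lower = 0)
  if (!inherits(weight, "weight_spec")) stop_invalid("'weight' must be a weight_spec")
  b0 <- if (is.null(urgency)) bound else urgency$b
  if (reflect >= b0) stop_invalid("'reflect' must be below the bound")
  if (v0 < reflect || v0 >= b0) stop_invalid("'v0' must lie in [reflect, bound)")
  if (reflect < 0 && is.finite(reflect) && inhibition > 0) {
    warning("reflect < 0 with inhibition > 0: negative DVs excite the other ",
            "accumulator; consider reflect = 0", call. = FALSE)
  }
  structure(list(rho = rho, bound = bound, reflect = reflect, leak = leak,
                 inhibition = inhibition, v0 = v0, sigma_eta = sigma_eta,
                 weight = weight, ndt = ndt, urgency = urgency),
            class = "race_spec")
}

#' Simulate the competing-accumulator model
#'
#' @param spec a [race_spec()].
#' @param stim a [gaussian_stimulus()] ensemble (accumulator 1 receives +s,
#'   accumulator 2 receives -s).
#' @param max_time hard cap (s) on stimulus extension for slow trials.
#' @param seed optional integer seed.
#' @return a `decision_trials` data frame as in [simulate_ddm()] (rt task);
#'   attribute `n_ties` counts simultaneous-crossing coin flips.
#' @export
simulate_race <- function(spec, stim, max_time = 20, seed = NULL) {
  if (!inherits(spec, "race_spec")) stop_invalid("'spec' must be a race_spec")
  if (!inherits(stim, "stimulus_ensemble")) {
    stop_invalid("'stim' must be a stimulus_ensemble")
  }
  w0 <- evaluate_weights(spec$weight, 0)
  rho_prime <- race_noise_correlation(spec$rho, w0, stim$sigma_s, spec$sigma_eta)
  with_seed(seed, .run_race(spec, stim, rho_prime, max_time))
}

.run_race <- function(spec, stim, rho_prime, max_time) {
  values <- stim$values
  n <- nrow(values)
  K <- ncol(values)
  dt <- stim$frame_dt
  w <- evaluate_weights(spec$weight, (seq_len(K) - 1L) * dt)
  t_end <- seq_len(K) * dt
  bounds <- if (is.null(spec$urgency)) rep(spec$bound, K) else
    bound_profile(t_end, spec$urgency)

  L <- spec$leak; I <- spec$inhibition
  base <- spec$v0 * (L + I)
  se <- spec$sigma_eta
  # correlated-noise mixing coefficients
  if (se > 0) {
    a2 <- rho_prime
    b2 <- sqrt(1 - rho_prime^2)
  }

  v1 <- rep(spec$v0, n); v2 <- rep(spec$v0, n)
  choice <- integer(n); dtime <- rep(NA_real_, n); crossed <- logical(n)
  active <- seq_len(n)
  n_ties <- 0L
  k <- 0L
  k_max <- floor(max_time / dt)
  mu_act <- stim$trial_mean

  while (length(active) > 0L && k < k_max) {
    k <- k + 1L
    if (k <= K) {
      s <- values[active, k]
      w_k <- w[k]
      b_k <- bounds[k]
    } else {
      s <- stats::rnorm(length(active), mu_act, stim$sigma_s)
      w_k <- evaluate_weights(spec$weight, (k - 1L) * dt)
      b_k <- if (is.null(spec$urgency)) spec$bound else bound_profile(k * dt, spec$urgency)
    }
    o1 <- v1[active]; o2 <- v2[active]
    d1 <- w_k * s - L * o1 - I * o2 + base
    d2 <- -w_k * s - L * o2 - I * o1 + base
    if (se > 0) {
      z1 <- stats::rnorm(length(active))
      z2 <- stats::rnorm(length(active))
      d1 <- d1 + se * z1
      d2 <- d2 + se * (a2 * z1 + b2 * z2)
    }
    n1 <- pmax(o1 + d1, spec$reflect)
    n2 <- pmax(o2 + d2, spec$reflect)
    v1[active] <- n1
    v2[active] <- n2
    up1 <- n1 >= b_k
    up2 <- n2 >= b_k
    hit <- up1 | up2
    if (any(hit)) {
      ch <- integer(sum(hit))
      both <- up1[hit] & up2[hit]
      ch[!both] <- ifelse(up1[hit][!both], 1L, 2L)
      if (any(both)) {
        n_ties <- n_ties + sum(both)
        ch[both] <- sample(1:2, sum(both), replace = TRUE)
      }
      idx <- active[hit]
      choice[idx] <- ch
      dtime[idx] <- k * dt
      crossed[idx] <- TRUE
      active <- active[!hit]
      mu_act <- mu_act[!hit]
    }
  }

  n_censored <- sum(!crossed)
  if (n_censored > 0L) {
    message(sprintf("%d of %d trials did not cross within %.3g s; censored",
                    n_censored, n, max_time))
  }
  rt <- dtime
  if (!is.null(spec$ndt)) {
    ok <- which(crossed)
    rt[ok] <- dtime[ok] + sample_ndt(spec$ndt, length(ok))
  }
  out <- data.frame(trial = seq_len(n), choice = choice, decision_time = dtime,
                    rt = rt, crossed = crossed, terminal_dv = NA_real_)
  out$choice[!crossed] <- NA_integer_
  structure(out, frame_dt = dt, task = "rt", n_censored = n_censored,
            n_ties = n_ties, class = c("decision_trials", "data.frame"))
}
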