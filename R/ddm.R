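# Frame-based drift-diffusion decision simulators.
#
# Accumulation runs at stimulus-frame resolution: the decision variable (DV)
# gains w(t_k) * s_k + eta_k per frame, with eta_k ~ N(0, sigma_eta^2). The DV
# is absorbed at the first frame whose update crosses the (possibly
# collapsing) bound; no sub-frame interpolation is attempted, because kernels
# are estimated at frame resolution anyway.

#' Collapsing-bound (urgency) specification
#'
#' Hyperbolic bound collapse \eqn{B(t) = b - u_\infty t / (t + \tau_{1/2})}:
#' the bound starts at `b`, loses half of its asymptotic reduction `u_inf` by
#' time `tau_half`, and approaches `b - u_inf`.
#'
#' @param b initial bound height (> 0).
#' @param u_inf asymptotic reduction in bound height (0 <= u_inf <= b).
#' @param tau_half time (s) at which half the reduction is reached (> 0).
#' @return object of class `urgency_spec`.
#' @export
urgency_spec <- function(b, u_inf, tau_half) {
  check_scalar(b, "b", lower = .Machine$double.eps)
  check_scalar(u_inf, "u_inf", lower = 0, upper = b)
  check_scalar(tau_half, "tau_half", lower = .Machine$double.eps)
  structure(list(b = b, u_inf = u_inf, tau_half = tau_half),
            class = "urgency_spec")
}

#' Bound height under a collapsing-bound specification
#'
#' @param t time(s) in seconds, >= 0.
#' @param spec an [urgency_spec()], or NULL for a missing urgency (returns NA).
#' @return bound height at each `t`; monotone non-increasing.
#' @examples
#' bound_profile(c(0, 0.4), urgency_spec(60, 60, 0.4))  # 60, 30
#' @export
bound_profile <- function(t, spec) {
  if (!inherits(spec, "urgency_spec")) stop_invalid("'spec' must be an urgency_spec")
  if (any(t < 0)) stop_invalid("'t' must be non-negative")
  spec$b - spec$u_inf * t / (t + spec$tau_half)
}

#' Analytic upper-bound absorption probability for a zero-drift DDM
#'
#' For a diffusion with zero overall drift between absorbing bounds at -B and
#' +B, a decision variable currently at `dv` reaches the upper bound first
#' with probability (B + dv) / (2B).
#'
#' @param dv current decision-variable value(s), |dv| <= B.
#' @param B bound height (> 0).
#' @return probability of upper-bound absorption.
#' @examples
#' bound_crossing_prob(15, 30)  # 0.75
#' @export
bound_crossing_prob <- function(dv, B) {
  check_scalar(B, "B", lower = .Machine$double.eps)
  if (any(abs(dv) > B)) stop_invalid("|dv| must not exceed the bound B")
  (B + dv) / (2 * B)
}

#' Non-decision-time specification
#'
#' Sensory/motor latency added to the bound-crossing time to form the observed
#' reaction time. The Gaussian family is truncated at zero (negative latencies
#' are impossible); the gamma family is moment-matched to (mean, sd) and
#' provides right-skewed latencies.
#'
#' @param mean_T0 mean non-decision time (s, >= 0).
#' @param sd_T0 standard deviation (s, >= 0).
#' @param family `"gaussian"` (truncated at 0) or `"gamma"` (moment-matched).
#' @return object of class `ndt_spec`.
#' @export
ndt_spec <- function(mean_T0, sd_T0, family = c("gaussian", "gamma")) {
  family <- match.arg(family)
  check_scalar(mean_T0, "mean_T0", lower = 0)
  check_scalar(sd_T0, "sd_T0", lower = 0)
  structure(list(family = family, mean_T0 = mean_T0, sd_T0 = sd_T0),
            class = "ndt_spec")
}

#' Sample non-decision times
#'
#' @param spec an [ndt_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return vector of n non-negative latencies (seconds).
#' @export
sample_ndt <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "ndt_spec")) stop_invalid("'spec' must be an ndt_spec")
  check_scalar(n, "n", lower = 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (spec$sd_T0 == 0) return(rep(spec$mean_T0, n))
  with_seed(seed, {
    if (spec$family == "gaussian") {
      # rejection sampling from the zero-truncated Gaussian
      out <- stats::rnorm(n, spec$mean_T0, spec$sd_T0)
      bad <- which(out < 0)
      while (length(bad) > 0L) {
        out[bad] <- stats::rnorm(length(bad), spec$mean_T0, spec$sd_T0)
        bad <- bad[out[bad] < 0]
      }
      out
    } else {
      shape <- (spec$mean_T0 / spec$sd_T0)^2
      rate <- spec$mean_T0 / spec$sd_T0^2
      stats::rgamma(n, shape = shape, rate = rate)
    }
  })
}

#' Drift-diffusion model specification (frame-based units)
#'
#' Parameters of the frame-based DDM. The bound is in accumulated-evidence
#' units (same units as `weight * stimulus`); `sigma_eta` is the per-frame
#' internal-noise sd. An [urgency_spec()] replaces the constant bound by a
#' collapsing one; an [ndt_spec()] adds non-decision time to the reported RT.
#'
#' @param bound absorbing bound height B (> 0); `Inf` gives unbounded
#'   integration (fixed-duration designs only).
#' @param sigma_eta per-frame internal noise sd (>= 0).
#' @param weight a [weight_spec()] giving w(t); default constant 1.
#' @param ndt optional [ndt_spec()].
#' @param urgency optional [urgency_spec()]; overrides `bound`.
#' @param start_point initial DV offset (|start_point| < bound).
#' @param drift_offset additive drift bias per second.
#' @return object of class `ddm_spec`.
#' @export
ddm_spec <- function(bound = 30, sigma_eta = 1, weight = weight_spec("constant"),
                     ndt = NULL, urgency = NULL, start_point = 0,
                     drift_offset = 0) {
  check_scalar(bound, "bound", lower = .Machine$double.eps, allow_inf = TRUE)
  check_scalar(sigma_eta, "sigma_eta", lower = 0)
  check_scalar(start_point, "start_point")
  check_scalar(drift_offset, "drift_offset")
  if (!inherits(weight, "weight_spec")) stop_invalid("'weight' must be a weight_spec")
  if (!is.null(ndt) && !inherits(ndt, "ndt_spec")) stop_invalid("'ndt' must be an ndt_spec")
  if (!is.null(urgency) && !inherits(urgency, "urgency_spec")) {
    stop_invalid("'urgency' must be an urgency_spec")
  }
  b0 <- if (is.null(urgency)) bound else urgency$b
  if (is.finite(b0) && abs(start_point) >= b0) {
    stop_invalid("|start_point| must be smaller than the initial bound")
  }
  structure(list(bound = bound, sigma_eta = sigma_eta, weight = weight,
                 ndt = ndt, urgency = urgency, start_point = start_point,
                 drift_offset = drift_offset),
            class = "ddm_spec")
}

# Bound height at frame-end times for a ddm_spec (vectorised over t).
.spec_bound <- function(spec, t) {
  if (is.null(spec$urgency)) rep(spec$bound, length(t)) else
    bound_profile(t, spec$urgency)
}

#' Simulate drift-diffusion decisions on a stimulus ensemble
#'
#' Integrates weighted stimulus plus internal noise frame by frame. In the
#' `"rt"` task the trial ends at the first bound crossing and the reaction
#' time adds a non-decision-time sample; trials that have not crossed by the
#' end of the supplied ensemble continue on internally generated stimulus
#' frames (same per-trial mean and sigma_s) up to `max_time`, after which they
#' are censored (`crossed = FALSE`) with a message. In the `"fixed"` task the
#' stimulus duration is fixed: the DV freezes on crossing (absorbing bound)
#' and uncrossed trials choose by the sign of the terminal DV (ties broken at
#' random); the full stimulus enters kernel estimation downstream, emulating
#' the experimenter's ignorance of the covert decision time.
#'
#' @param spec a [ddm_spec()].
#' @param stim a [gaussian_stimulus()] ensemble.
#' @param task `"rt"` (subject-terminated) or `"fixed"` (fixed duration).
#' @param max_time hard cap (s) on stimulus extension in the rt task.
#' @param seed optional integer seed.
#' @return A `decision_trials` data frame with columns `trial`, `choice`
#'   (1 = upper bound / positive evidence), `decision_time`, `rt`, `crossed`,
#'   `terminal_dv` (fixed task; NA otherwise), plus attributes `frame_dt`,
#'   `task`, and `n_censored`.
#' @export
simulate_ddm <- function(spec, stim, task = c("rt", "fixed"),
                         max_time = 20, seed = NULL) {
  task <- match.arg(task)
  if (!inherits(spec, "ddm_spec")) stop_invalid("'spec' must be a ddm_spec")
  if (!inherits(stim, "stimulus_ensemble")) {
    stop_invalid("'stim' must be a stimulus_ensemble")
  }
  if (task == "rt" && !is.finite(spec$bound) && is.null(spec$urgency)) {
    stop_invalid("an rt task requires a finite bound")
  }
  with_seed(seed, .run_ddm(spec, stim, task, max_time))
}

.run_ddm <- function(spec, stim, task, max_time) {
  values <- stim$values
  n <- nrow(values)
  K <- ncol(values)
  dt <- stim$frame_dt
  t_end <- (seq_len(K)) * dt              # frame-end times, bound checks
  w <- evaluate_weights(spec$weight, (seq_len(K) - 1L) * dt)
  bounds <- .spec_bound(spec, t_end)

  dv <- rep(spec$start_point, n)
  choice <- integer(n)
  dtime <- rep(NA_real_, n)
  crossed <- logical(n)
  active <- seq_len(n)

  for (k in seq_len(K)) {
    s <- values[active, k]
    inc <- w[k] * s + spec$drift_offset * dt
    if (spec$sigma_eta > 0) inc <- inc + stats::rnorm(length(active), 0, spec$sigma_eta)
    dv[active] <- dv[active] + inc
    if (is.finite(bounds[k])) {
      up <- dv[active] >= bounds[k]
      dn <- dv[active] <= -bounds[k]
      hit <- up | dn
      if (any(hit)) {
        idx <- active[hit]
        choice[idx] <- ifelse(up[hit], 1L, 2L)
        dtime[idx] <- t_end[k]
        crossed[idx] <- TRUE
        active <- active[!hit]
      }
    }
    if (length(active) == 0L) break
  }

  if (task == "rt" && length(active) > 0L) {
    # extend the stimulus stream beyond the supplied ensemble (not retained)
    k <- K
    k_max <- floor(max_time / dt)
    mu_act <- stim$trial_mean[active]
    while (length(active) > 0L && k < k_max) {
      k <- k + 1L
      t_k <- k * dt
      w_k <- evaluate_weights(spec$weight, (k - 1L) * dt)
      b_k <- .spec_bound(spec, t_k)
      s <- stats::rnorm(length(active), mu_act, stim$sigma_s)
      inc <- w_k * s + spec$drift_offset * dt
      if (spec$sigma_eta > 0) inc <- inc + stats::rnorm(length(active), 0, spec$sigma_eta)
      dv[active] <- dv[active] + inc
      up <- dv[active] >= b_k
      dn <- dv[active] <= -b_k
      hit <- up | dn
      if (any(hit)) {
        idx <- active[hit]
        choice[idx] <- ifelse(up[hit], 1L, 2L)
        dtime[idx] <- t_k
        crossed[idx] <- TRUE
        active <- active[!hit]
        mu_act <- mu_act[!hit]
      }
    }
  }

  terminal_dv <- rep(NA_real_, n)
  n_censored <- 0L
  if (task == "fixed") {
    T_s <- K * dt
    uncrossed <- which(!crossed)
    terminal_dv <- dv   # crossed trials froze at the bound
    if (length(uncrossed) > 0L) {
      sgn <- sign(dv[uncrossed])
      ties <- sgn == 0
      if (any(ties)) sgn[ties] <- sample(c(-1, 1), sum(ties), replace = TRUE)
      choice[uncrossed] <- ifelse(sgn > 0, 1L, 2L)
    }
    dtime[uncrossed] <- T_s  # decision_time keeps the covert crossing time
    rt <- rep(T_s, n)
  } else {
    cens <- which(!crossed)
    n_censored <- length(cens)
    if (n_censored > 0L) {
      message(sprintf("%d of %d trials did not cross within %.3g s; censored",
                      n_censored, n, max_time))
      choice[cens] <- NA_integer_
      dtime[cens] <- NA_real_
    }
    rt <- dtime
    if (!is.null(spec$ndt)) {
      ok <- which(crossed)
      rt[ok] <- dtime[ok] + sample_ndt(spec$ndt, length(ok))
    }
  }

  out <- data.frame(trial = seq_len(n), choice = choice,
                    decision_time = dtime, rt = rt, crossed = crossed,
                    terminal_dv = terminal_dv)
  structure(out, frame_dt = dt, task = task, n_censored = n_censored,
            class = c("decision_trials", "data.frame"))
}

#' Simulate unbounded fixed-duration integration
#'
#' Convenience wrapper for a fixed-duration design with no decision bound:
#' the DV integrates the whole stimulus and the choice is the sign of the
#' terminal DV (ties broken at random).
#'
#' @inheritParams simulate_ddm
#' @return a `decision_trials` data frame (see [simulate_ddm()]); all trials
#'   have `crossed = FALSE` and a recorded `terminal_dv`.
#' @export
simulate_unbounded_ddm <- function(spec, stim, seed = NULL) {
  spec$bound <- Inf
  spec$urgency <- NULL
  simulate_ddm(spec, stim, task = "fixed", seed = seed)
}

#' @export
print.decision_trials <- function(x, ...) {
  n <- nrow(x)
  ok <- x$crossed | attr(x, "task") == "fixed"
  cat(sprintf("Decision trials: %d (%s task, frame_dt = %.4g s)\n",
              n, attr(x, "task"), attr(x, "frame_dt")))
  cat(sprintf("  P(choice 1) = %.3f; median RT = %.3g s; censored = %d\n",
              mean(x$choice[ok] == 1L, na.rm = TRUE),
              stats::median(x$rt[ok], na.rm = TRUE),
              attr(x, "n_censored")))
  invisible(x)
}
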