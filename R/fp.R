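# Fokker-Planck first-passage machinery for bounded drift diffusion, and a
# fine-timestep diffusion simulator used as its Monte-Carlo cross-check.

#' Solve the Fokker-Planck equation for bounded drift diffusion
#'
#' Propagates the decision-variable density under
#' \eqn{\partial_t p = [-\partial_v \mu + 0.5 \sigma_e^2 \partial_v^2] p}
#' between absorbing bounds at \eqn{\pm B} from a delta initial condition at
#' 0, and returns the probability absorbed at each bound per time step.
#' Implicit (backward-Euler) finite differences on a uniform grid; the flux
#' bookkeeping conserves probability to machine precision.
#'
#' @param mu drift rate: a scalar (constant drift, 1/s evidence units) or a
#'   vector giving the drift at each solver step.
#' @param bound bound height B (> 0); the decision variable starts at 0.
#' @param t_max solver horizon in seconds (ignored when `mu` is a vector,
#'   whose length sets the horizon).
#' @param sigma_e diffusion (momentary evidence) sd per sqrt(second); 1 by
#'   convention.
#' @param dt solver time step (s), default 0.5 ms.
#' @param nv grid points across `[-B, B]` including the boundaries
#'   (odd; default 2^9 + 1).
#' @return An object of class `fp_solution`: list with `times` (end of each
#'   step), `flux_upper`, `flux_lower` (probability absorbed per step),
#'   `survivor_mass` (probability still between the bounds after each step),
#'   `conservation_error`, and the solver settings.
#' @examples
#' fp <- fp_solve(mu = 0, bound = 1, t_max = 4)
#' sum(fp$flux_upper)  # 0.5 by symmetry
#' @export
fp_solve <- function(mu, bound, t_max = NULL, sigma_e = 1, dt = 5e-4,
                     nv = 513) {
  check_scalar(bound, "bound", lower = .Machine$double.eps)
  check_scalar(sigma_e, "sigma_e", lower = .Machine$double.eps)
  check_scalar(dt, "dt", lower = .Machine$double.eps)
  check_scalar(nv, "nv", lower = 5)
  nv <- as.integer(nv)
  if (nv %% 2L == 0L) nv <- nv + 1L   # odd grid so the delta sits on a node
  if (length(mu) == 1L) {
    if (is.null(t_max)) stop_invalid("'t_max' is required for constant drift")
    nsteps <- ceiling(t_max / dt)
    mu <- rep(as.numeric(mu), nsteps)
  }
  sol <- fp_solve_cpp(as.numeric(mu), bound, sigma_e, dt, nv)
  cons <- abs(1 - sum(sol$flux_upper) - sum(sol$flux_lower) - sol$mass_direct)
  if (cons > 1e-6) {
    stop_invalid(sprintf("probability loss %.3g exceeds solver tolerance", cons))
  }
  structure(
    list(times = seq_along(mu) * dt, flux_upper = sol$flux_upper,
         flux_lower = sol$flux_lower, survivor_mass = sol$survivor_mass,
         conservation_error = cons, bound = bound, sigma_e = sigma_e,
         dt = dt, nv = nv),
    class = "fp_solution")
}

#' @export
print.fp_solution <- function(x, ...) {
  cat(sprintf("Fokker-Planck solution: horizon %.3g s (dt = %.3g s, %d grid points)\n",
              max(x$times), x$dt, x$nv))
  cat(sprintf("  P(upper) = %.4f, P(lower) = %.4f, surviving = %.3g (conservation error %.2g)\n",
              sum(x$flux_upper), sum(x$flux_lower),
              x$survivor_mass[length(x$survivor_mass)], x$conservation_error))
  invisible(x)
}

#' Closed-form absorption probability and mean decision time
#'
#' Reference values for constant-drift diffusion between absorbing bounds at
#' \eqn{\pm B} starting at 0: the upper-bound absorption probability is
#' \eqn{1 / (1 + e^{-2\mu B / \sigma^2})}; with zero drift the mean decision
#' time is \eqn{B^2/\sigma^2}.
#'
#' @param mu constant drift.
#' @param bound bound height.
#' @param sigma_e diffusion sd.
#' @return list with `p_upper` and (zero drift only) `mean_dt`.
#' @export
fp_reference <- function(mu, bound, sigma_e = 1) {
  p_up <- 1 / (1 + exp(-2 * mu * bound / sigma_e^2))
  md <- if (abs(mu) < 1e-12) bound^2 / sigma_e^2 else
    (bound / mu) * tanh(mu * bound / sigma_e^2)
  list(p_upper = p_up, mean_dt = md)
}

#' RT densities by choice: bound-crossing flux convolved with non-decision time
#'
#' Convolves the per-step absorbed flux at each bound with the discretized
#' non-decision-time density, yielding the predicted reaction-time density
#' for each choice at the solver resolution.
#'
#' @param fp an [fp_solve()] solution.
#' @param ndt an [ndt_spec()] (or NULL for no non-decision time).
#' @return list with `times`, `upper`, `lower` (densities per second; each
#'   integrates to the corresponding choice probability).
#' @export
fp_rt_density <- function(fp, ndt = NULL) {
  if (!inherits(fp, "fp_solution")) stop_invalid("'fp' must be an fp_solution")
  dt <- fp$dt
  if (is.null(ndt) || (!is.null(ndt) && ndt$sd_T0 == 0 && ndt$mean_T0 == 0)) {
    return(list(times = fp$times, upper = fp$flux_upper / dt,
                lower = fp$flux_lower / dt))
  }
  if (!inherits(ndt, "ndt_spec")) stop_invalid("'ndt' must be an ndt_spec")
  g <- .ndt_mass(ndt, dt)
  up <- .conv_causal(fp$flux_upper, g)
  lo <- .conv_causal(fp$flux_lower, g)
  list(times = seq_along(up) * dt, upper = up / dt, lower = lo / dt)
}

# Discretized non-decision-time probability mass on the solver grid
# (bin k covers ((k-1)dt, k dt]; Gaussian family truncated at 0).
.ndt_mass <- function(ndt, dt) {
  if (ndt$sd_T0 == 0) {
    k <- max(1L, round(ndt$mean_T0 / dt))
    g <- numeric(k); g[k] <- 1
    return(g)
  }
  if (ndt$family == "gaussian") {
    hi <- ndt$mean_T0 + 6 * ndt$sd_T0
    edges <- seq(0, hi + dt, by = dt)
    g <- diff(stats::pnorm(edges, ndt$mean_T0, ndt$sd_T0))
    g / (1 - stats::pnorm(0, ndt$mean_T0, ndt$sd_T0))
  } else {
    shape <- (ndt$mean_T0 / ndt$sd_T0)^2
    rate <- ndt$mean_T0 / ndt$sd_T0^2
    hi <- ndt$mean_T0 + 10 * ndt$sd_T0
    edges <- seq(0, hi + dt, by = dt)
    diff(stats::pgamma(edges, shape = shape, rate = rate))
  }
}

# FFT-based causal ("open") convolution of two mass vectors.
.conv_causal <- function(x, g) {
  stats::convolve(x, rev(g), type = "open")
}

#' Simulate first-passage times of a drift diffusion by Euler-Maruyama
#'
#' Fine-timestep Monte-Carlo oracle for the Fokker-Planck solver: simulates
#' \eqn{dv = \mu(t) dt + \sigma_e dW} between absorbing bounds at \eqn{\pm B}.
#' A Brownian-bridge correction accounts for within-step bound crossings,
#' removing the O(sqrt(dt)) discretisation bias of naive Euler stepping.
#'
#' @param n number of trials.
#' @param mu drift: scalar or per-step vector (1/s units).
#' @param bound bound height.
#' @param t_max horizon (s); trials alive at the horizon are censored.
#' @param sigma_e diffusion sd.
#' @param dt simulation step (s).
#' @param bridge logical; apply the within-step crossing correction.
#' @param start initial decision-variable value (|start| < bound).
#' @param seed optional integer seed.
#' @return data frame with `choice` (1 upper / 2 lower / NA censored) and
#'   `decision_time`.
#' @export
simulate_diffusion <- function(n, mu, bound, t_max = 10, sigma_e = 1,
                               dt = 1e-3, bridge = TRUE, start = 0,
                               seed = NULL) {
  check_scalar(n, "n", lower = 1)
  check_scalar(bound, "bound", lower = .Machine$double.eps)
  check_scalar(start, "start", lower = -bound, upper = bound)
  n <- as.integer(n)
  nsteps <- if (length(mu) > 1L) length(mu) else ceiling(t_max / dt)
  mu_t <- rep_len(as.numeric(mu), nsteps)
  sdt <- sigma_e * sqrt(dt)
  with_seed(seed, {
    v <- rep(start, n)
    choice <- rep(NA_integer_, n)
    dtime <- rep(NA_real_, n)
    active <- seq_len(n)
    for (k in seq_len(nsteps)) {
      old <- v[active]
      new <- old + mu_t[k] * dt + sdt * stats::rnorm(length(active))
      up <- new >= bound
      dn <- new <= -bound
      if (bridge) {
        # within-step crossing probability for paths ending inside the bounds
        inside <- !up & !dn
        if (any(inside)) {
          o <- old[inside]; nw <- new[inside]
          p_up <- exp(-2 * (bound - o) * (bound - nw) / (sigma_e^2 * dt))
          p_dn <- exp(-2 * (bound + o) * (bound + nw) / (sigma_e^2 * dt))
          u <- stats::runif(length(o))
          bu <- u < p_up
          bd <- !bu & (u < p_up + p_dn)
          up[inside] <- bu
          dn[inside] <- bd
        }
      }
      hit <- up | dn
      if (any(hit)) {
        idx <- active[hit]
        choice[idx] <- ifelse(up[hit], 1L, 2L)
        dtime[idx] <- k * dt
        keepv <- new[!hit]
        active <- active[!hit]
        v[active] <- keepv
      } else {
        v[active] <- new
      }
      if (length(active) == 0L) break
    }
    data.frame(choice = choice, decision_time = dtime)
  })
}
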