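# Maximum-likelihood fitting of drift-diffusion parameters to choice/RT data
# via the Fokker-Planck first-passage solution, and kernel prediction from
# the fitted parameters.
#
# Drift parameterizations ("drift" argument):
#   coherence              mu = gamma * C                 (per condition)
#   time_varying           mu(t) = gamma * C * (1 + beta1 t + beta2 t^2)
#   multi_feature          mu(t) = gamma_e s_e + gamma_n s_n + gamma_m s_m
#   multi_feature_tv       the above times (1 + beta1 t + beta2 t^2)
# The diffusion scale sigma_e is fixed at 1, so bound and sensitivity are in
# units of the momentary-evidence sd per sqrt(second).

#' Fit a drift-diffusion model to choices and reaction times
#'
#' Maximizes the joint likelihood of observed choices and RTs. For each
#' candidate parameter set the bound-crossing time distribution is obtained
#' from the Fokker-Planck equation and convolved with the non-decision-time
#' distribution; single-trial log densities (floored at 1e-10) are summed.
#' The optimizer (Nelder-Mead on log-transformed positive parameters) is
#' restarted from `n_restarts` random initial points at a 2x-coarsened solver
#' step; the best optimum is then polished at the requested resolution and
#' reported.
#'
#' @param trials data frame with columns `choice` (1 = upper/positive bound,
#'   2 = lower), `rt` (s), and -- for the coherence modes -- `condition`
#'   (signed stimulus strength, e.g. proportion coherence).
#' @param drift drift parameterization (see Details above).
#' @param stimulus a [face_features()] stream row-matched to `trials`
#'   (multi-feature modes only); per-trial feature fluctuations define a
#'   time-varying drift for each trial. Express feature values as fractions
#'   (morph/100) so the sensitivities share the per-unit-stimulus scale of
#'   the coherence mode.
#' @param n_restarts number of random restarts (default 10).
#' @param dt Fokker-Planck step for the likelihood (s).
#' @param nv Fokker-Planck grid points.
#' @param hessian compute standard errors from the numerical Hessian.
#' @param seed optional integer seed (random restart draws).
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return An object of class `ddm_fit`: list with `coefficients` (named:
#'   bound, gamma or gamma_e/n/m, mean_T0, sd_T0, optionally beta1, beta2),
#'   `logLik`, `se`, `vcov`, `restarts` (log-likelihoods and convergence
#'   codes of the exploration stage), `converged`, `drift`, `n`, and solver
#'   settings.
#' @seealso [predict.ddm_fit()] for kernel prediction,
#'   [simulate.ddm_fit()] for forward simulation.
#' @export
ddm_fit <- function(trials,
                    drift = c("coherence", "time_varying", "multi_feature",
                              "multi_feature_tv"),
                    stimulus = NULL, n_restarts = 10, dt = 1e-3, nv = 513,
                    hessian = TRUE, seed = NULL, control = list()) {
  drift <- match.arg(drift)
  if (!all(c("choice", "rt") %in% names(trials))) {
    stop_invalid("'trials' needs columns 'choice' and 'rt'")
  }
  keep <- !is.na(trials$choice) & !is.na(trials$rt)
  trials <- trials[keep, , drop = FALSE]
  if (!all(trials$choice %in% c(1, 2))) stop_invalid("choices must be coded 1/2")
  if (any(trials$rt <= 0)) stop_invalid("RTs must be positive")
  multi <- drift %in% c("multi_feature", "multi_feature_tv")
  if (multi) {
    if (!inherits(stimulus, "face_feature_stream")) {
      stop_invalid("multi-feature drift needs a face_feature_stream 'stimulus'")
    }
    if (sum(keep) != dim(stimulus$values)[1]) {
      # stimulus rows must match the retained trials
      stimulus$values <- stimulus$values[keep, , , drop = FALSE]
    }
  } else {
    if (!"condition" %in% names(trials)) {
      stop_invalid("coherence drift needs a 'condition' column")
    }
    if (length(unique(abs(trials$condition))) < 2L) {
      stop_invalid("need at least two distinct stimulus strengths")
    }
  }

  tv <- drift %in% c("time_varying", "multi_feature_tv")
  make_negll <- function(step, grid) {
    nsteps <- ceiling((max(trials$rt) + 2 * step) / step)
    rt_bin <- pmax(1L, as.integer(round(trials$rt / step)))
    .fit_objective(trials, drift, stimulus, step, grid, nsteps, rt_bin)$negll
  }
  # restarts explore on a coarsened solver (2x step, half the grid); the best
  # optimum is then polished at the requested resolution
  negll_coarse <- make_negll(2 * dt, (nv - 1) %/% 2 + 1)
  negll <- make_negll(dt, nv)

  par_names <- if (multi) c("bound", "gamma_e", "gamma_n", "gamma_m",
                            "mean_T0", "sd_T0")
               else c("bound", "gamma", "mean_T0", "sd_T0")
  if (tv) par_names <- c(par_names, "beta1", "beta2")

  min_rt <- min(trials$rt)
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      st <- c(
        bound = exp(stats::runif(1, log(0.4), log(3))),
        if (multi) stats::setNames(exp(stats::runif(3, log(1), log(30))),
                                   c("gamma_e", "gamma_n", "gamma_m"))
        else c(gamma = exp(stats::runif(1, log(1), log(40)))),
        mean_T0 = stats::runif(1, 0.3, 0.9) * min_rt,
        sd_T0 = exp(stats::runif(1, log(0.02), log(0.2))))
      if (tv) st <- c(st, beta1 = stats::rnorm(1, 0, 0.5),
                      beta2 = stats::rnorm(1, 0, 0.5))
      st
    })
  })

  to_opt <- function(p) {          # log-transform positive parameters
    q <- p
    pos <- !grepl("^beta", names(p))
    q[pos] <- log(p[pos])
    q
  }
  from_opt <- function(q) {
    p <- q
    pos <- !grepl("^beta", names(q))
    p[pos] <- exp(q[pos])
    p
  }
  ctl <- utils::modifyList(list(maxit = if (tv) 200 else 150, reltol = 1e-6),
                           control)

  restarts <- data.frame(restart = seq_len(n_restarts), logLik = NA_real_,
                         convergence = NA_integer_)
  best <- NULL
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(to_opt(starts[[i]]), function(q) negll_coarse(from_opt(q)),
                   method = "Nelder-Mead", control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) next
    restarts$logLik[i] <- -fit$value
    restarts$convergence[i] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_invalid("all restarts failed; check the data scale")
  best <- stats::optim(best$par, function(q) negll(from_opt(q)),
                       method = "Nelder-Mead",
                       control = utils::modifyList(
                         ctl, list(maxit = if (tv) 600 else 400,
                                   reltol = 1e-8)))

  coefs <- from_opt(best$par)
  names(coefs) <- par_names
  se <- vc <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(best$par, function(q) negll(from_opt(q))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      vc_t <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc_t)) {
        # delta method back to the natural scale (d exp(q)/dq = exp(q))
        J <- diag(ifelse(grepl("^beta", par_names), 1, coefs), length(coefs))
        vc <- J %*% vc_t %*% J
        dimnames(vc) <- list(par_names, par_names)
        se <- sqrt(pmax(diag(vc), 0))
        names(se) <- par_names
      }
    }
  }

  structure(
    list(coefficients = coefs, logLik = -best$value, se = se, vcov = vc,
         restarts = restarts,
         converged = best$convergence == 0L ||
           any(restarts$convergence == 0L, na.rm = TRUE),
         drift = drift, n = nrow(trials), dt = dt, nv = nv,
         conditions = if (!multi) sort(unique(trials$condition)) else NULL),
    class = "ddm_fit")
}

# Build the negative log-likelihood closure. Conditions of opposite sign
# share one Fokker-Planck solve (mirror symmetry: flux_up(-mu) = flux_lo(mu)).
.fit_objective <- function(trials, drift, stimulus, dt, nv, nsteps, rt_bin) {
  env <- new.env(parent = emptyenv())
  floor_lik <- 1e-10
  tgrid <- (seq_len(nsteps) - 0.5) * dt
  multi <- drift %in% c("multi_feature", "multi_feature_tv")
  tv <- drift %in% c("time_varying", "multi_feature_tv")

  if (!multi) {
    cond <- trials$condition
    ucond <- sort(unique(abs(cond)))
    groups <- lapply(ucond, function(cc) {
      idx <- list(pos = which(cond == cc), neg = if (cc > 0) which(cond == -cc)
                  else integer(0))
      # condition-specific solver horizon: decision times never exceed the
      # longest RT observed in that condition
      idx$nsteps <- min(nsteps,
                        ceiling(max(trials$rt[c(idx$pos, idx$neg)]) / dt) + 2L)
      idx
    })
    env$negll <- function(p) {
      if (any(!is.finite(p))) return(1e10)
      ndt <- ndt_spec(p[["mean_T0"]], p[["sd_T0"]])
      g <- .ndt_mass(ndt, dt)
      total <- 0
      for (gi in seq_along(ucond)) {
        cc <- ucond[gi]
        ns_c <- groups[[gi]]$nsteps
        mu <- p[["gamma"]] * cc
        mu_t <- if (tv) mu * (1 + p[["beta1"]] * tgrid[seq_len(ns_c)] +
                                p[["beta2"]] * tgrid[seq_len(ns_c)]^2)
                else rep(mu, ns_c)
        sol <- fp_solve_cpp(mu_t, p[["bound"]], 1, dt, as.integer(nv))
        d_up <- .conv_causal(sol$flux_upper, g)
        d_lo <- .conv_causal(sol$flux_lower, g)
        idx <- groups[[gi]]
        if (length(idx$pos)) {
          b <- rt_bin[idx$pos]
          li <- ifelse(trials$choice[idx$pos] == 1L, d_up[b], d_lo[b])
          li[is.na(li)] <- 0
          total <- total + sum(log(pmax(li / dt, floor_lik)))
        }
        if (length(idx$neg)) {   # mirrored condition: swap the two fluxes
          b <- rt_bin[idx$neg]
          li <- ifelse(trials$choice[idx$neg] == 1L, d_lo[b], d_up[b])
          li[is.na(li)] <- 0
          total <- total + sum(log(pmax(li / dt, floor_lik)))
        }
      }
      -total
    }
  } else {
    vals <- stimulus$values
    frame_dt <- stimulus$frame_dt
    n_tr <- dim(vals)[1]
    # per-step frame index for expanding frame-resolution drift to solver grid
    frame_of <- pmin(dim(vals)[2], floor(tgrid / frame_dt) + 1L)
    env$negll <- function(p) {
      if (any(!is.finite(p))) return(1e10)
      ndt <- ndt_spec(p[["mean_T0"]], p[["sd_T0"]])
      g <- .ndt_mass(ndt, dt)
      mod <- if (tv) 1 + p[["beta1"]] * tgrid + p[["beta2"]] * tgrid^2 else 1
      total <- 0
      for (i in seq_len(n_tr)) {
        mu_f <- p[["gamma_e"]] * vals[i, , 1] + p[["gamma_n"]] * vals[i, , 2] +
          p[["gamma_m"]] * vals[i, , 3]
        mu_t <- mu_f[frame_of] * mod
        sol <- fp_solve_cpp(mu_t, p[["bound"]], 1, dt, as.integer(nv))
        d <- if (trials$choice[i] == 1L) .conv_causal(sol$flux_upper, g)
             else .conv_causal(sol$flux_lower, g)
        li <- d[rt_bin[i]]
        if (is.na(li)) li <- 0
        total <- total + log(max(li / dt, floor_lik))
      }
      -total
    }
  }
  env
}

#' Evaluate the choice/RT log-likelihood at given parameters
#'
#' Computes the same joint choice/RT log-likelihood that [ddm_fit()]
#' maximizes, at a fixed parameter vector -- useful for likelihood-ratio
#' comparisons between nested drift parameterizations.
#'
#' @inheritParams ddm_fit
#' @param params named vector with the parameters of the chosen drift mode
#'   (see [ddm_fit()]); `beta1`/`beta2` default to 0 when absent in a
#'   time-varying mode.
#' @return scalar log-likelihood.
#' @export
ddm_loglik <- function(trials, params,
                       drift = c("coherence", "time_varying", "multi_feature",
                                 "multi_feature_tv"),
                       stimulus = NULL, dt = 1e-3, nv = 513) {
  drift <- match.arg(drift)
  keep <- !is.na(trials$choice) & !is.na(trials$rt)
  trials <- trials[keep, , drop = FALSE]
  if (drift %in% c("time_varying", "multi_feature_tv")) {
    for (b in c("beta1", "beta2")) {
      if (!b %in% names(params)) params[b] <- 0
    }
  }
  nsteps <- ceiling((max(trials$rt) + 2 * dt) / dt)
  rt_bin <- pmax(1L, as.integer(round(trials$rt / dt)))
  negll <- .fit_objective(trials, drift, stimulus, dt, nv, nsteps,
                          rt_bin)$negll
  -negll(params)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Drift-diffusion fit (%s drift), %d trials\n", x$drift, x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("log-likelihood %.2f (%d restarts, best %s)\n", x$logLik,
              nrow(x$restarts),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.ddm_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients,
               se = if (is.null(object$se)) NA_real_ else object$se)
  tab <- cbind(tab, z = tab[, 1] / tab[, 2])
  structure(list(coefficients = tab, logLik = object$logLik,
                 drift = object$drift, n = object$n,
                 converged = object$converged, restarts = object$restarts),
            class = "summary.ddm_fit")
}

#' @export
print.summary.ddm_fit <- function(x, ...) {
  cat(sprintf("Drift-diffusion fit (%s drift), %d trials\n", x$drift, x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("log-likelihood %.2f; restart spread %.2f\n", x$logLik,
              diff(range(x$restarts$logLik, na.rm = TRUE))))
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) object$coefficients

#' @export
logLik.ddm_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
vcov.ddm_fit <- function(object, ...) object$vcov

#' Forward-simulate choices and RTs from a fitted model
#'
#' Draws first-passage times from the fitted diffusion (Euler-Maruyama with
#' bridge correction) for given conditions and adds sampled non-decision
#' times -- a parametric-bootstrap generator for the fitted model.
#'
#' @param object a [ddm_fit()] (coherence-type drift).
#' @param nsim trials per condition.
#' @param seed optional integer seed.
#' @param conditions signed stimulus strengths (default: those seen in the
#'   fit).
#' @param t_max simulation horizon (s).
#' @param ... unused.
#' @return data frame with `condition`, `choice`, `rt`.
#' @export
simulate.ddm_fit <- function(object, nsim = 1000, seed = NULL,
                             conditions = NULL, t_max = 10, ...) {
  if (object$drift %in% c("multi_feature", "multi_feature_tv")) {
    stop_invalid("use predict(..., newdata = <face stream>) for multi-feature fits")
  }
  if (is.null(conditions)) conditions <- object$conditions
  p <- object$coefficients
  ndt <- ndt_spec(p[["mean_T0"]], p[["sd_T0"]])
  with_seed(seed, {
    out <- lapply(conditions, function(cc) {
      nst <- ceiling(t_max / 1e-3)
      tg <- (seq_len(nst) - 0.5) * 1e-3
      mu <- if (object$drift == "time_varying") {
        p[["gamma"]] * cc * (1 + p[["beta1"]] * tg + p[["beta2"]] * tg^2)
      } else p[["gamma"]] * cc
      d <- simulate_diffusion(nsim, mu, p[["bound"]], t_max = t_max)
      ok <- !is.na(d$choice)
      data.frame(condition = cc, choice = d$choice[ok],
                 rt = d$decision_time[ok] + sample_ndt(ndt, sum(ok)))
    })
    do.call(rbind, out)
  })
}

#' Predict psychophysical kernels from a fitted model
#'
#' Forwards the fitted parameters into the frame-based simulator on fresh
#' mean-zero stimulus streams and computes the psychophysical kernel of the
#' simulated choices -- the model's prediction for the experimental kernel.
#' The fitted sensitivity (per second per unit stimulus) is converted to a
#' per-frame weight `gamma * frame_dt`, and the unit diffusion becomes
#' per-frame internal noise of sd `sqrt(frame_dt)`.
#'
#' @param object a [ddm_fit()].
#' @param newdata a mean-zero [gaussian_stimulus()] ensemble (coherence
#'   drift) or [face_features()] stream (multi-feature drift). Row count sets
#'   the number of simulated trials.
#' @param align kernel alignment(s) to return.
#' @param seed optional integer seed for the forward simulation.
#' @param ... unused.
#' @return list with `kernel` (a `psych_kernel`, or named list per feature /
#'   per alignment), `trials` (the simulated `decision_trials`), and
#'   `median_rt`.
#' @export
predict.ddm_fit <- function(object, newdata, align = "stimulus",
                            seed = NULL, ...) {
  p <- object$coefficients
  multi <- object$drift %in% c("multi_feature", "multi_feature_tv")
  tv <- object$drift %in% c("time_varying", "multi_feature_tv")
  ndt <- ndt_spec(p[["mean_T0"]], p[["sd_T0"]])
  if (multi) {
    if (!inherits(newdata, "face_feature_stream")) {
      stop_invalid("multi-feature prediction needs a face_feature_stream")
    }
    fdt <- newdata$frame_dt
    # collapse the three feature streams into one drift stream (per frame)
    drive <- p[["gamma_e"]] * newdata$values[, , 1] +
      p[["gamma_n"]] * newdata$values[, , 2] +
      p[["gamma_m"]] * newdata$values[, , 3]
    if (tv) {
      tt <- (seq_len(ncol(drive)) - 1L) * fdt
      drive <- sweep(drive, 2L, 1 + p[["beta1"]] * tt + p[["beta2"]] * tt^2, "*")
    }
    stim_drive <- structure(
      list(values = drive * fdt, frame_dt = fdt, sigma_s = 0,
           trial_mean = rep(0, nrow(drive)), seed = NULL),
      class = "stimulus_ensemble")
    spec <- ddm_spec(bound = p[["bound"]], sigma_eta = sqrt(fdt),
                     weight = weight_spec("constant", gamma = 1), ndt = ndt)
    trials <- simulate_ddm(spec, stim_drive, task = "rt", seed = seed)
    kernel <- lapply(stats::setNames(align, align), function(a) {
      psych_kernel(newdata, trials, align = a)
    })
    if (length(align) == 1L) kernel <- kernel[[1L]]
  } else {
    if (!inherits(newdata, "stimulus_ensemble")) {
      stop_invalid("'newdata' must be a stimulus_ensemble of strength fluctuations")
    }
    fdt <- newdata$frame_dt
    wspec <- if (tv) {
      weight_spec("polynomial", gamma = p[["gamma"]] * fdt,
                  beta1 = p[["beta1"]], beta2 = p[["beta2"]])
    } else {
      weight_spec("constant", gamma = p[["gamma"]] * fdt)
    }
    spec <- ddm_spec(bound = p[["bound"]], sigma_eta = sqrt(fdt),
                     weight = wspec, ndt = ndt)
    trials <- simulate_ddm(spec, newdata, task = "rt", seed = seed)
    kernel <- lapply(stats::setNames(align, align), function(a) {
      psych_kernel(newdata, trials, align = a)
    })
    if (length(align) == 1L) kernel <- kernel[[1L]]
  }
  list(kernel = kernel, trials = trials,
       median_rt = stats::median(trials$rt[trials$crossed], na.rm = TRUE))
}
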