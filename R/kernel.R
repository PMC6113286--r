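# Psychophysical kernel estimation, normalization, and the kernel-weight
# distortion metric.
#
# The kernel is the time-resolved difference of mean stimulus fluctuations
# conditioned on the two choices,
#   K(t) = E[s(t) | choice 1, T >= t] - E[s(t) | choice 2, T >= t],
# estimated at frame resolution. In a reaction-time design a frame enters bin
# t only for trials whose RT is at least the bin time; in a fixed-duration
# design every trial contributes every frame. No smoothing is ever applied.

#' Estimate a psychophysical kernel
#'
#' Computes the stimulus-aligned or response-aligned kernel from mean-zero
#' (0% strength) trials. Stimulus alignment: bin k (onset `(k-1)*frame_dt`)
#' uses trials whose RT is at least the bin onset (the default inclusion
#' rule; set `inclusion = "offset"` to require RT past the frame offset).
#' Response alignment: the RT is rounded down to the onset of the last
#' stimulus frame and bins count backwards from the last fully displayed
#' frame, so bin time `-frame_dt` is the final pre-response frame.
#'
#' @param stim a [gaussian_stimulus()] ensemble or [face_features()] stream
#'   (one kernel per feature in the latter case).
#' @param trials a `decision_trials` data frame (or any data frame with
#'   columns `choice`, `rt`, optionally `crossed`) row-matched to `stim`.
#' @param align `"stimulus"` or `"response"`.
#' @param window kernel extent in seconds. Default: the median RT for rt
#'   tasks, the stimulus duration for fixed-duration tasks. Always capped at
#'   the stimulus duration.
#' @param inclusion stimulus-aligned inclusion rule: `"onset"` (default,
#'   RT >= frame onset) or `"offset"` (RT >= frame offset).
#' @return An object of class `psych_kernel`: data frame with `time`, `value`,
#'   `sem`, `n` (contributing trials), and attributes `alignment`,
#'   `normalization` (`"raw"`), `frame_dt`, `window_end`, `median_rt`,
#'   `scale_value`. For a face stream, a named list of three such kernels
#'   (class `psych_kernel_set`).
#' @export
psych_kernel <- function(stim, trials, align = c("stimulus", "response"),
                         window = NULL, inclusion = c("onset", "offset")) {
  align <- match.arg(align)
  inclusion <- match.arg(inclusion)
  if (inherits(stim, "face_feature_stream")) {
    ks <- lapply(seq_along(stim$feature_names), function(f) {
      m <- stim$values[, , f, drop = TRUE]
      .kernel_matrix(m, stim$frame_dt, trials, align, window, inclusion)
    })
    names(ks) <- stim$feature_names
    class(ks) <- "psych_kernel_set"
    return(ks)
  }
  if (!inherits(stim, "stimulus_ensemble")) {
    stop_invalid("'stim' must be a stimulus_ensemble or face_feature_stream")
  }
  .kernel_matrix(stim$values, stim$frame_dt, trials, align, window, inclusion)
}

.kernel_matrix <- function(values, dt, trials, align, window, inclusion) {
  if (nrow(values) != nrow(trials)) {
    stop_invalid("stimulus and trial table must have the same number of rows")
  }
  keep <- !is.na(trials$choice)
  if ("crossed" %in% names(trials) &&
      !is.null(attr(trials, "task")) && attr(trials, "task") == "rt") {
    keep <- keep & trials$crossed
  }
  choice <- trials$choice[keep]
  rt <- trials$rt[keep]
  if (!all(choice %in% c(1L, 2L))) stop_invalid("choices must be coded 1/2")
  if (length(unique(choice)) < 2L) {
    stop_invalid("both choice categories must be present")
  }
  n_frames <- ncol(values)
  duration <- n_frames * dt
  task <- attr(trials, "task")
  med_rt <- stats::median(rt)
  if (is.null(window)) {
    window <- if (!is.null(task) && task == "fixed") duration else med_rt
  }
  window <- min(window, duration)
  rows <- which(keep)
  is1 <- choice == 1L

  if (align == "stimulus") {
    n_bins <- max(1L, min(n_frames, floor(window / dt + 1e-9) + 1L))
    onsets <- (seq_len(n_bins) - 1L) * dt
    thresh <- if (inclusion == "onset") onsets else onsets + dt
    val <- sem <- rep(NA_real_, n_bins)
    ntr <- integer(n_bins)
    # trials sorted by rt descending: bin k uses the first m_k of them
    ord <- order(rt, decreasing = TRUE)
    rt_s <- rt[ord]
    is1_s <- is1[ord]
    rows_s <- rows[ord]
    c1 <- cumsum(is1_s); c2 <- cumsum(!is1_s)
    for (k in seq_len(n_bins)) {
      m_k <- sum(rt_s >= thresh[k])     # rt sorted desc -> first m_k rows
      if (m_k == 0L) next
      sk <- values[rows_s[seq_len(m_k)], k]
      n1 <- c1[m_k]; n2 <- c2[m_k]
      ntr[k] <- m_k
      if (n1 < 2L || n2 < 2L) next   # value stays NA, n records the trials
      g1 <- sk[is1_s[seq_len(m_k)]]
      g2 <- sk[!is1_s[seq_len(m_k)]]
      val[k] <- mean(g1) - mean(g2)
      sem[k] <- sqrt(stats::var(g1) / n1 + stats::var(g2) / n2)
    }
    if (anyNA(val)) {
      warning("bins with fewer than 2 trials per choice were set to NA",
              call. = FALSE)
    }
    times <- onsets
  } else {
    # response aligned: frame m_i = floor(rt/dt) is the last fully displayed
    # frame; bin j (time -j*dt) uses frame m_i - j + 1. Trials whose response
    # frame lies beyond the retained stimulus cannot be aligned and are
    # dropped.
    m_i <- floor(rt / dt + 1e-9)
    retained <- m_i <= n_frames
    if (!all(retained)) {
      rows <- rows[retained]
      is1 <- is1[retained]
      m_i <- m_i[retained]
    }
    n_bins <- max(1L, floor(window / dt + 1e-9))
    val <- sem <- rep(NA_real_, n_bins)
    ntr <- integer(n_bins)
    for (j in seq_len(n_bins)) {
      fr <- m_i - j + 1L
      use <- fr >= 1L
      if (!any(use)) next
      sk <- values[cbind(rows[use], fr[use])]
      g1 <- sk[is1[use]]
      g2 <- sk[!is1[use]]
      ntr[j] <- sum(use)
      if (length(g1) < 2L || length(g2) < 2L) next
      val[j] <- mean(g1) - mean(g2)
      sem[j] <- sqrt(stats::var(g1) / length(g1) + stats::var(g2) / length(g2))
    }
    times <- -seq_len(n_bins) * dt
  }

  out <- data.frame(time = times, value = val, sem = sem, n = ntr)
  structure(out, alignment = align, normalization = "raw", frame_dt = dt,
            window_end = window, median_rt = med_rt, scale_value = 1,
            class = c("psych_kernel", "data.frame"))
}

#' Total terminal-DV standard deviation of unbounded integration
#'
#' Discrete analogue of the terminal decision-variable variance of an
#' unbounded integrator over `n_frames` frames:
#' \eqn{\sigma_{tot}^2 = n \sigma_\eta^2 + \sigma_s^2 \sum_k w_k^2}.
#'
#' @param n_frames number of integrated frames.
#' @param frame_dt frame duration (s), used to evaluate the weights.
#' @param sigma_s per-frame stimulus sd.
#' @param sigma_eta per-frame internal noise sd.
#' @param weight a [weight_spec()].
#' @return sigma_tot (scalar sd, accumulated-evidence units).
#' @export
sigma_tot <- function(n_frames, frame_dt, sigma_s = 1, sigma_eta = 1,
                      weight = weight_spec("constant")) {
  w <- evaluate_weights(weight, (seq_len(n_frames) - 1L) * frame_dt)
  sqrt(n_frames * sigma_eta^2 + sigma_s^2 * sum(w^2))
}

#' Normalize a kernel for direct comparison with the sensory weights
#'
#' Divides the raw kernel by the analytic proportionality constant linking
#' kernels and weights: `2 * sigma_s^2 / B` for bounded accumulation (with a
#' collapsing bound, B is replaced by its average from stimulus onset to the
#' median RT) and `4 * sigma_s^2 / (sqrt(2*pi) * sigma_tot)` for unbounded
#' accumulation.
#'
#' @param kernel a `psych_kernel`.
#' @param model `"bounded"` or `"unbounded"`.
#' @param sigma_s per-frame stimulus sd used in the simulation/experiment.
#' @param bound bound height B (bounded model with constant bound).
#' @param urgency an [urgency_spec()]; if given, the scale uses the bound
#'   profile averaged over `[0, median_rt]`.
#' @param median_rt median RT (s); defaults to the kernel's stored value.
#' @param sigma_tot terminal-DV sd (unbounded model); see [sigma_tot()].
#' @return the kernel with `value`/`sem` divided by the scale; attributes
#'   `normalization` and `scale_value` updated.
#' @export
normalize_kernel <- function(kernel, model = c("bounded", "unbounded"),
                             sigma_s = 1, bound = NULL, urgency = NULL,
                             median_rt = NULL, sigma_tot = NULL) {
  model <- match.arg(model)
  if (!inherits(kernel, "psych_kernel")) stop_invalid("'kernel' must be a psych_kernel")
  check_scalar(sigma_s, "sigma_s", lower = 0)
  if (model == "bounded") {
    if (!is.null(urgency)) {
      if (is.null(median_rt)) median_rt <- attr(kernel, "median_rt")
      # time-average of the closed-form bound profile over [0, median RT]
      B <- stats::integrate(function(t) bound_profile(t, urgency),
                            0, median_rt)$value / median_rt
    } else if (!is.null(bound)) {
      B <- bound
    } else {
      stop_invalid("bounded normalization needs 'bound' or 'urgency'")
    }
    scale <- 2 * sigma_s^2 / B
  } else {
    if (is.null(sigma_tot)) {
      stop_invalid("unbounded normalization needs 'sigma_tot'")
    }
    scale <- 4 * sigma_s^2 / (sqrt(2 * pi) * sigma_tot)
  }
  kernel$value <- kernel$value / scale
  kernel$sem <- kernel$sem / scale
  attr(kernel, "normalization") <- model
  attr(kernel, "scale_value") <- scale
  kernel
}

#' Root-mean-square distortion between a kernel and the true weights
#'
#' \deqn{\mathrm{distortion} = \sqrt{\frac{1}{T_m}\sum_t (w(t) - K(t))^2}}
#' over the kernel's reported bins (NA bins are excluded). The kernel should
#' be normalized first so that it lives on the weight scale.
#'
#' @param kernel a `psych_kernel` (normalized).
#' @param weights a [weight_spec()] evaluated at the kernel bin times, or a
#'   numeric vector already on the kernel's time grid.
#' @return non-negative scalar RMSE.
#' @export
kernel_distortion <- function(kernel, weights) {
  if (!inherits(kernel, "psych_kernel")) stop_invalid("'kernel' must be a psych_kernel")
  w <- if (inherits(weights, "weight_spec")) {
    evaluate_weights(weights, pmax(kernel$time, 0))
  } else {
    if (length(weights) != nrow(kernel)) {
      stop_invalid("weights and kernel are on different time grids")
    }
    as.numeric(weights)
  }
  ok <- !is.na(kernel$value)
  sqrt(mean((w[ok] - kernel$value[ok])^2))
}

#' Average kernels across subjects
#'
#' Unweighted mean per bin across subjects, with the across-subject standard
#' error; the window is truncated to the shortest subject window (for RT
#' tasks this is the shortest median RT).
#'
#' @param kernels list of `psych_kernel` objects with equal bin width and
#'   alignment.
#' @return a `psych_kernel` whose `n` column counts subjects per bin.
#' @export
average_kernels <- function(kernels) {
  if (length(kernels) == 0L) stop_invalid("need at least one kernel")
  if (!all(vapply(kernels, inherits, TRUE, "psych_kernel"))) {
    stop_invalid("all elements must be psych_kernel objects")
  }
  aligns <- vapply(kernels, attr, "", "alignment")
  if (length(unique(aligns)) != 1L) stop_invalid("mixed kernel alignments")
  dts <- vapply(kernels, attr, 0, "frame_dt")
  if (max(abs(dts - dts[1])) > 1e-9) stop_invalid("mixed bin widths")
  n_bins <- min(vapply(kernels, nrow, 0L))
  mat <- vapply(kernels, function(k) k$value[seq_len(n_bins)],
                numeric(n_bins))
  mat <- matrix(mat, nrow = n_bins)
  m <- rowMeans(mat, na.rm = TRUE)
  nsub <- rowSums(!is.na(mat))
  sem <- apply(mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else 0
  })
  out <- data.frame(time = kernels[[1]]$time[seq_len(n_bins)], value = m,
                    sem = sem, n = nsub)
  structure(out, alignment = aligns[1],
            normalization = attr(kernels[[1]], "normalization"),
            frame_dt = dts[1],
            window_end = min(vapply(kernels, attr, 0, "window_end")),
            median_rt = min(vapply(kernels, attr, 0, "median_rt")),
            scale_value = attr(kernels[[1]], "scale_value"),
            class = c("psych_kernel", "data.frame"))
}

#' @export
print.psych_kernel <- function(x, ...) {
  cat(sprintf(
    "Psychophysical kernel: %d bins of %.4g s (%s-aligned, %s normalization)\n",
    nrow(x), attr(x, "frame_dt"), attr(x, "alignment"), attr(x, "normalization")))
  ok <- !is.na(x$value)
  cat(sprintf("  mean value %.4g (mean sem %.3g); window %.3g s\n",
              mean(x$value[ok]), mean(x$sem[ok]), attr(x, "window_end")))
  invisible(x)
}

#' Plot a psychophysical kernel with +/- 1 sem shading
#'
#' @param x a `psych_kernel`.
#' @param true_weights optional [weight_spec()] overlaid as a reference line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.psych_kernel <- function(x, true_weights = NULL, ...) {
  ok <- !is.na(x$value)
  graphics::plot(x$time[ok], x$value[ok], type = "l",
                 xlab = sprintf("time from %s (s)", attr(x, "alignment")),
                 ylab = "kernel", ...)
  graphics::polygon(c(x$time[ok], rev(x$time[ok])),
                    c(x$value[ok] + x$sem[ok], rev(x$value[ok] - x$sem[ok])),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$time[ok], x$value[ok])
  if (!is.null(true_weights)) {
    graphics::lines(x$time[ok], evaluate_weights(true_weights, pmax(x$time[ok], 0)),
                    lty = 2, col = 2)
  }
  invisible(x)
}

#' @export
print.psych_kernel_set <- function(x, ...) {
  cat(sprintf("Kernel set for features: %s\n", paste(names(x), collapse = ", ")))
  for (nm in names(x)) { cat(nm, ": "); print(x[[nm]]) }
  invisible(x)
}
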