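# Random-dot kinematograms and opponent motion-energy filtering.
#
# The stimulus is the classic three-set random-dot movie: dots are split into
# three interleaved sets shown on consecutive video frames; each set is
# replotted `displace_frames` (3) frames after it was last shown, when a
# Bernoulli(coherence) subset moves coherently along +x by
# speed * displace_frames / frame_rate degrees and the rest are replotted
# uniformly in the aperture. Motion energy is computed with two quadrature
# pairs of space-time separable filters (even/odd fourth-order Cauchy spatial
# profiles times biphasic temporal impulse responses); each pair's outputs
# are squared and summed, summed over space, and the two opponent energies
# are subtracted to give the net rightward energy per video frame.

#' Make a random-dot kinematogram
#'
#' @param coherence proportion of coherently displaced dots in [0, 1]; a
#'   scalar or a per-frame vector (e.g. a coherence step).
#' @param n_frames number of video frames.
#' @param aperture_deg aperture diameter (degrees).
#' @param deg_per_px spatial sampling (degrees per pixel).
#' @param frame_rate video frame rate (Hz).
#' @param speed coherent speed (deg/s).
#' @param density dot density (dots per deg^2 per second).
#' @param n_sets interleaved dot sets.
#' @param displace_frames replot lag in video frames.
#' @param direction +1 for rightward (+x) motion, -1 for leftward.
#' @param seed optional integer seed.
#' @return object of class `dot_movie`: list with `frames` (array
#'   `nx x ny x n_frames`, binary luminance) and the stimulus parameters.
#' @export
dot_movie <- function(coherence, n_frames, aperture_deg = 5,
                      deg_per_px = 0.05, frame_rate = 75, speed = 5,
                      density = 16.7, n_sets = 3, displace_frames = 3,
                      direction = 1, seed = NULL) {
  if (any(coherence < 0 | coherence > 1)) {
    stop_invalid("'coherence' must be in [0, 1]")
  }
  check_scalar(n_frames, "n_frames", lower = 1)
  check_scalar(aperture_deg, "aperture_deg", lower = .Machine$double.eps)
  n_frames <- as.integer(n_frames)
  coh <- rep_len(coherence, n_frames)
  radius <- aperture_deg / 2
  step <- direction * speed * displace_frames / frame_rate
  if (abs(step) >= aperture_deg) {
    stop_invalid("aperture smaller than one coherent displacement")
  }
  n_px <- ceiling(aperture_deg / deg_per_px) + 1L
  area <- pi * radius^2
  n_dots <- max(1L, round(density * area / frame_rate))

  rand_xy <- function(m) {
    # uniform in the circular aperture (rejection from the bounding square)
    x <- stats::runif(m, -radius, radius)
    y <- stats::runif(m, -radius, radius)
    bad <- which(x^2 + y^2 > radius^2)
    while (length(bad) > 0L) {
      x[bad] <- stats::runif(length(bad), -radius, radius)
      y[bad] <- stats::runif(length(bad), -radius, radius)
      bad <- bad[x[bad]^2 + y[bad]^2 > radius^2]
    }
    cbind(x, y)
  }

  with_seed(seed, {
    frames <- array(0, dim = c(n_px, n_px, n_frames))
    sets <- lapply(seq_len(n_sets), function(s) rand_xy(n_dots))
    for (k in seq_len(n_frames)) {
      s <- ((k - 1L) %% n_sets) + 1L
      if (k > n_sets) {
        xy <- sets[[s]]
        move <- stats::runif(n_dots) < coh[k]
        if (any(move)) {
          x <- xy[move, 1] + step
          y <- xy[move, 2]
          # wrap: dots leaving the aperture re-enter on the opposite side
          out <- x^2 + y^2 > radius^2
          if (any(out)) {
            chord <- 2 * sqrt(pmax(radius^2 - y[out]^2, 0))
            x[out] <- x[out] - sign(step) * chord
          }
          xy[move, 1] <- x
        }
        if (any(!move)) xy[!move, ] <- rand_xy(sum(!move))
        sets[[s]] <- xy
      }
      xy <- sets[[s]]
      ix <- pmin(n_px, pmax(1L, round(xy[, 1] / deg_per_px + (n_px + 1) / 2)))
      iy <- pmin(n_px, pmax(1L, round(xy[, 2] / deg_per_px + (n_px + 1) / 2)))
      frames[cbind(ix, iy, k)] <- 1
    }
    structure(list(frames = frames, deg_per_px = deg_per_px,
                   frame_rate = frame_rate, aperture_deg = aperture_deg,
                   coherence = coh, speed = speed, density = density,
                   n_sets = n_sets, displace_frames = displace_frames,
                   direction = direction, seed = seed),
              class = "dot_movie")
  })
}

#' Build the opponent motion-energy filter bank
#'
#' Spatial filters are even and odd fourth-order Cauchy functions
#' \eqn{f_1 = \cos^4\alpha \cos(4\alpha) e^{-y^2/2\omega_g^2}},
#' \eqn{f_2 = \cos^4\alpha \sin(4\alpha) e^{-y^2/2\omega_g^2}} with
#' \eqn{\alpha = \arctan(x / 0.35)} and \eqn{\omega_g = 0.05}; temporal
#' filters are \eqn{g_n(t) = (60t)^n e^{-60t}[1/n! - (60t)^2/(n+2)!]} for
#' n = 3, 5. The quadrature pairs f1 g1 + f2 g2 / f2 g1 - f1 g2 prefer one
#' direction and f1 g1 - f2 g2 / f2 g1 + f1 g2 the other.
#'
#' @param deg_per_px spatial sampling; must match the movie.
#' @param frame_rate temporal sampling (Hz).
#' @param x_support,y_support spatial half-extent (deg) at which the filters
#'   are truncated.
#' @param t_support temporal extent (s).
#' @param omega_g spatial Gaussian width (deg).
#' @param alpha_scale Cauchy scale (deg).
#' @param rate temporal rate constant (1/s).
#' @return object of class `motion_filters`: list with matrices `f1`, `f2`
#'   (x by y), vectors `g1`, `g2`, the grids, and the relative truncation
#'   error of each filter at its support edge.
#' @export
motion_filters <- function(deg_per_px = 0.05, frame_rate = 75,
                           x_support = 1.5, y_support = 0.25,
                           t_support = 0.3, omega_g = 0.05,
                           alpha_scale = 0.35, rate = 60) {
  xg <- seq(-x_support, x_support, by = deg_per_px)
  yg <- seq(-y_support, y_support, by = deg_per_px)
  tg <- seq(0, t_support, by = 1 / frame_rate)
  alpha <- atan(xg / alpha_scale)
  cx_even <- cos(alpha)^4 * cos(4 * alpha)
  cx_odd <- cos(alpha)^4 * sin(4 * alpha)
  gy <- exp(-yg^2 / (2 * omega_g^2))
  f1 <- outer(cx_even, gy)
  f2 <- outer(cx_odd, gy)
  gfun <- function(n, t) (rate * t)^n * exp(-rate * t) *
    (1 / factorial(n) - (rate * t)^2 / factorial(n + 2))
  g1 <- gfun(3, tg)
  g2 <- gfun(5, tg)
  trunc_err <- c(
    spatial = max(abs(cx_even[c(1, length(cx_even))])) / max(abs(cx_even)),
    temporal = max(abs(g1[length(g1)]), abs(g2[length(g2)])) / max(abs(g1)))
  structure(list(f1 = f1, f2 = f2, g1 = g1, g2 = g2, x = xg, y = yg, t = tg,
                 deg_per_px = deg_per_px, frame_rate = frame_rate,
                 truncation_error = trunc_err),
            class = "motion_filters")
}

# 2-D "same" linear convolution via FFT, centred on the (odd-sized) kernel.
.conv2_same <- function(mat, kern) {
  nx <- nrow(mat) + nrow(kern) - 1L
  ny <- ncol(mat) + ncol(kern) - 1L
  pm <- matrix(0, nx, ny); pm[seq_len(nrow(mat)), seq_len(ncol(mat))] <- mat
  pk <- matrix(0, nx, ny); pk[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- Re(stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE)) / (nx * ny)
  ox <- (nrow(kern) - 1L) %/% 2L
  oy <- (ncol(kern) - 1L) %/% 2L
  full[ox + seq_len(nrow(mat)), oy + seq_len(ncol(mat)), drop = FALSE]
}

#' Net opponent motion energy of a dot movie
#'
#' Convolves the movie with the four direction-selective spatiotemporal
#' filters, squares and sums each quadrature pair, sums over space, and
#' subtracts the two directions. Positive values indicate net energy in the
#' +x (rightward) direction.
#'
#' @param movie a [dot_movie()].
#' @param filters a [motion_filters()] bank (built on demand if missing).
#' @return numeric vector: net motion energy per video frame (arbitrary
#'   units), with attribute `per_direction` (a 2-column matrix of the
#'   right/left energies before subtraction).
#' @export
net_motion_energy <- function(movie, filters = NULL) {
  if (!inherits(movie, "dot_movie")) stop_invalid("'movie' must be a dot_movie")
  if (is.null(filters)) {
    filters <- motion_filters(deg_per_px = movie$deg_per_px,
                              frame_rate = movie$frame_rate)
  }
  if (abs(filters$deg_per_px - movie$deg_per_px) > 1e-12) {
    stop_invalid("filter and movie spatial scales differ")
  }
  fr <- movie$frames
  nt <- dim(fr)[3]
  # spatial stage: even- and odd-filtered movies
  s1 <- array(0, dim = dim(fr)); s2 <- array(0, dim = dim(fr))
  for (k in seq_len(nt)) {
    s1[, , k] <- .conv2_same(fr[, , k], filters$f1)
    s2[, , k] <- .conv2_same(fr[, , k], filters$f2)
  }
  # temporal stage: causal convolution with g1, g2
  tconv <- function(s, g) {
    out <- array(0, dim = dim(s))
    for (j in seq_along(g)) {
      if (g[j] == 0) next
      idx <- j:nt
      out[, , idx] <- out[, , idx] + g[j] * s[, , idx - j + 1L]
    }
    out
  }
  a11 <- tconv(s1, filters$g1)   # f1 g1
  a12 <- tconv(s1, filters$g2)   # f1 g2
  a21 <- tconv(s2, filters$g1)   # f2 g1
  a22 <- tconv(s2, filters$g2)   # f2 g2
  e_right <- (a11 + a22)^2 + (a21 - a12)^2
  e_left <- (a11 - a22)^2 + (a21 + a12)^2
  npx <- prod(dim(fr)[1:2])
  right <- colSums(matrix(e_right, npx, nt))
  left <- colSums(matrix(e_left, npx, nt))
  structure(right - left, per_direction = cbind(right = right, left = left))
}

#' Slope of mean motion energy versus coherence
#'
#' Least-squares calibration of the (linear) relation between average net
#' motion energy and motion coherence; the slope converts motion energies to
#' coherence-equivalent units via [energy_to_coherence()].
#'
#' @param coherences coherence level per group (>= 2 distinct levels).
#' @param mean_energies mean net motion energy per group (same length).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
coherence_energy_slope <- function(coherences, mean_energies) {
  if (length(unique(coherences)) < 2L) {
    stop_invalid("need at least two coherence levels")
  }
  if (length(coherences) != length(mean_energies)) {
    stop_invalid("inputs must have equal length")
  }
  fit <- stats::lm(mean_energies ~ coherences)
  ss_tot <- sum((mean_energies - mean(mean_energies))^2)
  r2 <- if (length(coherences) > 2L && ss_tot > 0) {
    1 - sum(stats::residuals(fit)^2) / ss_tot
  } else 1
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r_squared = r2)
}

#' Convert motion energies to coherence-equivalent units
#'
#' @param energies net motion energy values.
#' @param slope calibration slope from [coherence_energy_slope()] (> 0).
#' @return `energies / slope`.
#' @export
energy_to_coherence <- function(energies, slope) {
  check_scalar(slope, "slope")
  if (slope <= 0) stop_invalid("calibration slope must be positive")
  energies / slope
}

#' Response lag of the motion-energy pipeline to a coherence step
#'
#' Given the (ensemble-mean) net energy of movies containing a coherence
#' step, returns the lag in video frames from the step to the half-rise of
#' the energy response -- the effective delay with which stimulus
#' fluctuations appear in the motion energies.
#'
#' @param mean_energy mean net energy per frame across the movie ensemble.
#' @param step_frame frame index at which the coherence stepped up.
#' @param settle_frames frames at the end treated as the post-step plateau.
#' @return lag in video frames (can be fractional).
#' @export
energy_step_lag <- function(mean_energy, step_frame, settle_frames = 10) {
  nt <- length(mean_energy)
  if (step_frame >= nt) stop_invalid("step_frame beyond the movie")
  base <- mean(mean_energy[seq_len(step_frame)])
  plateau <- mean(mean_energy[(nt - settle_frames + 1L):nt])
  half <- base + 0.5 * (plateau - base)
  post <- mean_energy[(step_frame + 1L):nt]
  k <- which(post >= half)[1]
  if (is.na(k)) return(NA_real_)
  # linear interpolation inside the crossing frame
  prev <- if (k == 1L) base else post[k - 1L]
  frac <- if (post[k] == prev) 0 else (half - prev) / (post[k] - prev)
  (k - 1L) + frac
}
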