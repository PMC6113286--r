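---
title: "Decision models and the psychophysical kernel: methods and design notes"
author: "revkernel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision models and the psychophysical kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(revkernel)
```

This vignette documents the models the package implements, the estimation
conventions, the numerical choices, and the limits of what the synthetic
validation can show. It is the design record for maintainers; the README
shows the user-facing workflow.

## The model family

**Evidence streams.** Stimuli are piecewise-constant per display frame: one
independent Gaussian draw per frame with per-trial mean C (signed coherence
or morph) and per-frame sd `sigma_s`. This is a deliberate modelling choice,
not an approximation of continuous white noise: psychophysical displays
update at frame rate (13.3 ms for random-dot motion at 75 Hz, 106.7 ms for
masked face-morph updates), the kernel is estimated at that same resolution,
and the analytic kernel scales below are exact in these discrete units with
`sigma_s` defined per frame.

**Bounded drift diffusion.** The decision variable gains
`w(t_k) s_k + eta_k` per frame (`eta_k ~ N(0, sigma_eta^2)`) and is absorbed
at the first frame whose update reaches ±B. The absorbed frame is the
decision time; no sub-frame interpolation is attempted because kernels
cannot resolve sub-frame timing anyway. The cost is an O(frame) overshoot
bias — the effective bound sits about `0.58 * sd(per-frame evidence)` above
B — which is visible only in quantities sensitive to the absolute bound
(about 0.7% at B = 30) and is asserted as a bounded bias in the tests. For
analyses that need the continuous-time limit (the Fokker–Planck
cross-checks, the Eq.-style bound-crossing probability), the package instead
uses `simulate_diffusion`, an Euler–Maruyama simulator with a
Brownian-bridge within-step crossing correction that removes the
O(sqrt(dt)) first-passage bias.

**Kernel identities.** With constant bound and no non-decision time, the
stimulus-aligned kernel of a reaction-time task equals
`(2 sigma_s^2 / B) w(t)`; for unbounded fixed-duration integration it is
`(4 sigma_s^2 / (sqrt(2 pi) sigma_tot)) w(t)` with
`sigma_tot^2 = n sigma_eta^2 + sigma_s^2 sum(w_k^2)` (discrete form). Both
are implemented in `normalize_kernel`; with a collapsing bound the scale
uses the bound profile averaged from stimulus onset to the median RT, which
is the convention that keeps the normalized kernel comparable to w(t)
while the bound is falling. The unbounded scale uses the small-weight
approximation `w^2 sigma_s^2 << sigma_tot^2`; at the default study scale
(75 frames, w near 1) the neglected term is below 1%.

**Non-decision time.** Gaussian, truncated at zero and renormalized —
negative latencies are physically impossible and the untruncated tail at the
default (mean 0.3 s, sd 0.1 s) is only 0.13%. A moment-matched gamma family
is provided for exploring right-skewed latencies; it is a generic stand-in
for any skewed family, not a claim about the true latency distribution.

**Urgency.** Implemented as the hyperbolic collapsing bound
`B(t) = b - u_inf * t / (t + tau_half)`. In the race model, urgency is also
implemented as a collapsing absorbing bound; the equivalence of an additive
urgency signal with anti-correlated inputs to a falling bound is relied
upon, not separately simulated.

**Competing accumulators.** Two units receive opposite stimulus drive
`[+s, -s]`, leak (L), mutual inhibition (I), a stable point at the common
starting value v0, correlated internal noise, a reflective floor R, and
absorbing ceilings. Design choices where the dynamics are underdetermined:

* L and I are expressed per frame (the regime of interest has
  L + I = 0.006 per 13.3-ms frame); the time base is stated in the docs and
  kernels across regimes should be compared shape-wise.
* The reflective bound is a projection (clamp after the Euler step), the
  "firing rates cannot be negative" reading, not an elastic reflection.
* Simultaneous crossings within one frame are resolved by a fair coin flip
  and counted in an attribute; at the default parameters they are rare.
* R < 0 with I > 0 lets a negative DV excite the competitor, which is
  biologically suspect; the constructor warns and the leak/inhibition
  regime uses R = 0.
* The internal-noise correlation rho' is derived from the requested input
  correlation rho via the variance identity using the weight at t = 0;
  with time-varying weights the realized input correlation drifts with
  w(t)^2, which is documented rather than corrected.

## Kernel estimation conventions

* One bin per stimulus frame; bin timestamps are frame onsets. No smoothing
  is ever applied.
* Stimulus-aligned inclusion: a trial contributes to bin t if its RT is at
  least the bin onset (`inclusion = "offset"` switches to the
  frame-offset rule). The partially viewed final frame therefore counts.
* Response alignment rounds the RT down to the onset of the last stimulus
  frame; bin `-frame_dt` is the last *fully displayed* frame before that
  point. Trials whose response frame lies beyond the retained stimulus
  array cannot be aligned and are dropped — silently truncating them
  instead would contaminate late bins with pre-decision evidence (this was
  caught by the validation suite during development).
* Windows default to the median RT (reaction-time tasks) or the stimulus
  duration (fixed-duration), and bins past the window are simply not
  reported. Bins with fewer than two trials for either choice are NA with
  a warning. Per-bin standard errors are across trials; across-subject
  averages (`average_kernels`) recompute the sem across subjects and
  truncate to the shortest median RT.
* Censored trials (no crossing by the extension cap, default 20 s) are
  excluded from kernels with a logged count.
* Kernel errors are weakly correlated *across bins* (all bins share the
  same realized choice labels), so omnibus trend statistics computed over
  bins (rank correlations, regressions) are mildly anticonservative under
  the null; the validation suite relies on them only where the trend is
  far from marginal.

## Fokker–Planck solver and ML fitting

The first-passage problem is solved with implicit (backward-Euler) finite
differences on a uniform grid over [-B, +B] (default 2^9 + 1 points
including the boundaries, dt = 0.5 ms for standalone solves), delta initial
condition at 0, absorbing boundaries. The per-step absorbed flux is read
from the updated boundary-adjacent density in the exact discrete form that
telescopes with the interior update, so probability is conserved to machine
precision by construction (measured ~1e-12 over 10^4 steps); accuracy
against closed forms is ~1e-4 on absorption probabilities. Backward Euler
was chosen over Crank–Nicolson because the delta initial condition
provokes oscillations in the latter; the O(dt) temporal bias is negligible
at RT scales.

The likelihood of a (choice, RT) pair convolves the choice-specific flux
with the discretized non-decision-time density (FFT convolution) and floors
the per-trial density at 1e-10 before logging, preventing -Inf from
horizon effects. Conditions of opposite sign share one solve by mirror
symmetry. Fitting details:

* Drift modes: `mu = gamma C` per condition; time-varying
  `mu(t) = gamma C (1 + beta1 t + beta2 t^2)`; multi-feature
  `mu(t) = gamma_e s_e + gamma_n s_n + gamma_m s_m` (per-trial solves using
  each trial's actual feature fluctuations, sigma_e^2 = 1); and the
  combination. Sensitivities are per second per unit stimulus, with the
  diffusion sd fixed at 1 defining the evidence units.
* Nelder–Mead on log-transformed positive parameters, 10 random restarts
  (log-uniform boxes: B in [0.4, 3], gamma in [1, 40], sd_T0 in
  [0.02, 0.2], T0 a uniform fraction of the fastest RT). Restarts explore
  on a 2x-coarsened solver (double step, half grid); the best optimum is
  polished at full resolution. The solver step for fitting defaults to
  1 ms, and the beta-augmented fits in the validation suite use 2 ms: the
  flux-timing bias these introduce (~0.5–1 ms) is three orders of
  magnitude below the non-decision-time sd they trade against, and the
  recovery harness confirms unbiased estimates at these settings.
* Standard errors come from the numerical Hessian at the optimum
  (delta-method back-transformed); `vcov`, `logLik`, `simulate`
  (parametric bootstrap via the bridge-corrected diffusion) and `predict`
  (kernel prediction via the frame-based simulator) follow the standard
  fitted-model interface.
* `predict` converts the fitted per-second sensitivity to a per-frame
  weight `gamma * frame_dt` and the unit diffusion to per-frame internal
  noise `sqrt(frame_dt)`, then simulates fresh mean-zero streams and runs
  the same kernel estimator as for data — so predicted and measured
  kernels share every estimation convention.

## Motion energy

Dot movies follow the three-set interleaving convention: each set is
replotted three video frames after it was shown (40 ms), a
Bernoulli(coherence) subset displaced by `speed * 3 / frame_rate` degrees,
the rest replotted uniformly. Dots displaced out of the circular aperture
re-enter on the opposite side, preserving density. Spatial sampling is
0.05 deg/pixel; the even/odd Cauchy pair (omega_g = 0.05 deg, scale
0.35 deg) is truncated at ±1.5 deg in x and the biphasic temporal filters
(rate 60/s, t in seconds) at 300 ms, with the truncation error reported by
`motion_filters` (<2%). Convolutions are exact linear (FFT with
zero-padding) so the opponent symmetry is exact: mirror-flipping a movie
negates the net energy to machine precision, and a blank movie gives
exactly zero. The orientation axis is horizontal; other directions are
obtained by rotating the movie into filter coordinates. The step-response
lag is summarized as the half-rise time of the ensemble-mean energy after
a coherence step — a plateau-robust statistic; with the default filters it
falls at 4–5 video frames (~60 ms).

## Synthetic data: what it does and does not emulate

The generators reproduce the stimulus statistics of the two tasks — frame
rates (13.3 / 106.7 ms), the coherence set {0, 3.2, 6.4, 12.8, 25.6,
51.2%}, the seven morph levels {−50…+50%} with 20%-morph feature sd and
rejection resampling outside ±100% (analytic rejection rate 0.184%,
matching the quoted 0.18%) — and the decision-side parameters used across
the validation suite (B = 30 and 60 in per-frame evidence units, NDT 0.3 ±
0.1 s, urgency b = 60, u_inf = 60, tau_half = 0.4 s, race regimes rho =
−0.2, R = −10, L + I = 0.006/frame at ratios 0.5–2). One regime choice
deserves a note: the non-decision-time study uses B = 12, which puts the
median RT near 1.1 s — the scale of real reaction times in these tasks —
because the kernel signature of a 300-ms latency is a property of its
*ratio* to the RT; at B = 30 (median RT ~5 s) the dilution is only a few
percent per bin and no estimator could resolve it at any practical trial
count. Where a quantity is
needed that no task specification pins down, one value was chosen and
documented: per-frame coherence-equivalent fluctuations of sd 0.2 for the
closed-loop fitting study (the scale such converted motion energies
plausibly take), and a 20-s stimulus-extension cap for non-crossing trials.

What passing tests do *not* show: real observers contribute non-stationary
sensitivity, sequential dependencies, lapses, and motor variability absent
from these generators; the ML fitter is well-specified here by
construction, whereas on real data the within-trial fluctuations it
ignores inflate the effective diffusion (a ~5–10% sensitivity bias the
closed-loop test deliberately retains by generating training data with
fluctuating streams). Kernel agreement at the Monte-Carlo floor on
synthetic data bounds implementation error, not model adequacy.

## Validation scales and known limitations

Simulation sizes in the validation suite are one to two orders of magnitude
below figure-grade runs (10^5–2x10^5 trials versus 10^6): per-bin kernel
sems scale as ~sqrt(2/n) per choice and every threshold in the suite was
set from that arithmetic. One consequence is documented in the suite
itself: at 2x10^5 trials the RMSE between a *perfectly recovered* bounded
kernel and the true weight is dominated by per-bin Monte-Carlo noise at
about 0.08, so the stricter 0.05 figure-grade distortion is only reachable
from ~4x10^5 trials upward; the corresponding assertion is kept at the
stricter value and fails for that stated reason rather than being widened.

Other limitations: the fitter does not implement hierarchical pooling
across subjects; the race model is simulate-only (fitting it is out of
scope, as its fitted regimes approximate the DDM's line-attractor
dynamics); multi-feature fits solve one Fokker–Planck equation per trial
per likelihood evaluation and are practical at hundreds, not thousands, of
trials; and kernel significance is per-bin sem only (no cluster
permutation).
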