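# Shared fixture builders for the test suite. Everything is generated in
# code; sizes are kept small except where a statistical check needs power.

# A tiny deterministic ensemble with hand-set values.
hand_stimulus <- function(values, frame_dt = 1 / 75, sigma_s = 1) {
  structure(list(values = values, frame_dt = frame_dt, sigma_s = sigma_s,
                 trial_mean = rowMeans(values), seed = NULL),
            class = "stimulus_ensemble")
}

# A minimal trial table matching a hand stimulus.
hand_trials <- function(choice, rt, task = "rt", frame_dt = 1 / 75) {
  structure(data.frame(trial = seq_along(choice), choice = choice,
                       decision_time = rt, rt = rt,
                       crossed = rep(TRUE, length(choice)),
                       terminal_dv = NA_real_),
            frame_dt = frame_dt, task = task, n_censored = 0L,
            class = c("decision_trials", "data.frame"))
}

# Mean of a Gaussian truncated to [lo, hi] (oracle for the face sampler).
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
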