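# Shared fixture builders. All synthetic inputs are built in code at test
# time; seeds are fixed so every run sees identical data.

# Reference-coded fixed-effect truth implied by a logit cell-mean matrix
# (rows placebo/MPH, columns weeks): intercept, arm main, week mains,
# interactions — the same coding the model matrix uses.
truth_fixed_effects <- function(cells) {
  ref <- 1
  others <- seq_len(ncol(cells))[-ref]
  c(cells["placebo", ref],
    cells["MPH", ref] - cells["placebo", ref],
    cells["placebo", others] - cells["placebo", ref],
    (cells["MPH", others] - cells["MPH", ref]) -
      (cells["placebo", others] - cells["placebo", ref]))
}

# A small complete trial with fixed seed, no withdrawals (used by model
# tests where ITT zero-imputation would contaminate truth recovery).
small_trial <- function(n = 20, seed = 101, dropouts = 0) {
  generate_trial(generator_config(n_participants = n, n_dropouts = dropouts,
                                  seed = seed))
}

# Daily MEMS timestamps at given clock hours over consecutive days.
mems_times <- function(hours, start = as.Date("2020-03-01")) {
  days <- seq_along(hours) - 1
  keep <- !is.na(hours)
  as.POSIXct(start, tz = "UTC") + 86400 * days[keep] + 3600 * hours[keep]
}

# Quiet single fit with shared defaults.
quick_fit <- function(data, outcome = "pill_logit",
                      priors = default_priors(), seed = 1, ...) {
  fit_lmm(data, model_spec(outcome), priors, seed = seed, ...)
}
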