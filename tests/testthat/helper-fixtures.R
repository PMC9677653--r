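# Shared fixtures, built in code. Heavy objects are memoised per test run.

base_params <- function() load_params()

# A plain mortality model with constant-ish hazard, for engine tests.
toy_mortality <- function(shape = 1, scale = 12, chronic_hr = 1.5) {
  mortality_model(shape = shape, scale = scale, chronic_hr = chronic_hr)
}

# Parameter set in which every distribution is a point mass.
fixed_params <- function() {
  p <- base_params()
  p$params$low <- p$params$mean
  p$params$high <- p$params$mean
  p$params$dist <- "fixed"
  p
}

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# Calibrated mortality: the shipped fixture (validated against a fresh
# calibration in the acceptance suite).
cal_mortality <- function() memo("cal", calibrated_mortality())

default_cohort <- function() memo("cohort", generate_cohort(generator_spec()))
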