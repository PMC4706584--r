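# Shared fixtures, all built in code at test time.

ref_params <- function() structural_parameters()

# Final published model (Table-1 values) via the shipped config.
ref_model <- function() reference_model()

# Base model without covariate effects, same variability.
base_model <- function() {
  m <- reference_model()
  population_model(theta = m$theta, omega = m$omega,
                   sigma_prop = m$sigma_prop, sigma_add = m$sigma_add)
}

# A small two-arm dataset simulated from `model` at a compact 7-cycle design.
small_trial <- function(model, n = 24, seed = 7, n_cycles = 7,
                        schedule = NULL) {
  subj <- generate_covariates(n, trial_design(), seed = seed)
  if (is.null(schedule))
    schedule <- list(SC = c(21 * (1:6), 126 + c(1, 2, 4, 7, 14), 147),
                     IV = c(90 / 1440, 21 * (1:6), 126 + c(1, 2, 4, 7, 14),
                            147))
  simulate_population(model, subj, n_cycles = n_cycles, schedule = schedule,
                      seed = seed + 1)
}

# Hand-built event table for IO tests.
toy_event_table <- function() {
  data.frame(
    ID = c(1, 1, 1, 2, 2),
    TIME = c(0, 21, 42, 0, 21),
    AMT = c(600, NA, NA, 544, NA),
    RATE = c(0, 0, 0, 544 / 0.0625, 0),
    DV = c(NA, 40.2, 55.1, NA, 30.5),
    EVID = c(1, 0, 0, 1, 0),
    MDV = c(1, 0, 0, 1, 0),
    CMT = c(1, 2, 2, 2, 2),
    WT = 68, ALT = 19,
    ARM = c("SC", "SC", "SC", "IV", "IV"))
}
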