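# Shared fixtures, built in code at test time.

base_inputs <- base_case_inputs()
lt_default <- base_inputs$life_table
lt_zero <- life_table(data.frame(age = c(0, 120), annual_death_prob = c(0, 0)))
clin3 <- clinical_parameters(horizon_years = 3)
clin30 <- clinical_parameters(horizon_years = 30)

# deterministic base-case run for one arm at a given horizon
base_run <- function(arm, horizon) {
  run_cohort(clinical_parameters(horizon_years = horizon), arm, lt_default)
}

# degenerate (zero-variance) uncertainty specs for the whole default set
degenerate_specs <- function(inputs = base_inputs) {
  lapply(default_psa_specs(inputs), function(s)
    uncertainty_spec(s$parameter, "degenerate", s$mean))
}
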