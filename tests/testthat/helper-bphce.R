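# shared fixtures, all built in code

# base case with a zero-mortality life table, to inspect transition
# entries before the background-mortality adjustment
params_no_mortality <- function(row_mode = "residual") {
  p <- base_case_parameters()
  p$life_table <- build_life_table_standin(calibration_target = 0)
  p$options$row_mode <- row_mode
  p
}

# cohort ICER at a horizon, both arms
cohort_icer <- function(params, horizon) {
  compute_icer(run_cohort(params, "combination", horizon, trace = FALSE),
               run_cohort(params, "monotherapy", horizon, trace = FALSE))
}
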