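# shared fixtures: small life tables and parameter variants built in code

# flat life table: constant annual q at every age, terminal q = 1
flat_table <- function(q, terminal_age = 100) {
  life_table(0:terminal_age, c(rep(q, terminal_age), 1))
}

# the analysis-default synthetic life table (calibrated once per test run)
default_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- calibrate_life_table(74)
    tab
  }
})

# parameters with all stochastic risks off: no transplant excess mortality,
# no graft failure, no cardiac disease, background mortality only
no_excess_params <- function(...) {
  thal_params(lambda_death_cohort = 0, q_fail_q1 = 0, q_fail_q2 = 0,
              p_cardiac_annual = 0, cardiac_death_rate = 0,
              rr_btict_death = 1, ...)
}

# cohort of explicit records
records_of <- function(times, events) {
  survival_records(seq_along(times), times, events)
}
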