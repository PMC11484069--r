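# Shared fixtures, built once per test run. All synthetic; no external data.

human_profile <- function() burn_profile("human", weight = 70, tbsa = 0.4)
pig_profile <- function() burn_profile("pig", weight = 31.7, tbsa = 0.4)

.fixture_env <- new.env()

human_params <- function() {
  if (is.null(.fixture_env$hpar)) {
    .fixture_env$hpar <- derive_constrained_parameters(
      human_profile(), param_registry("human"))
  }
  .fixture_env$hpar
}

pig_params <- function() {
  if (is.null(.fixture_env$ppar)) {
    .fixture_env$ppar <- derive_constrained_parameters(
      pig_profile(), param_registry("pig"))
  }
  .fixture_env$ppar
}

human_rt <- function(maintenance = FALSE, perturb_on = TRUE) {
  burnsim:::runtime_constants(human_profile(), human_params(),
                              maintenance = maintenance,
                              perturb_on = perturb_on)
}

# Cumulative infused volume of a realized piecewise-constant schedule at t.
cum_infusion <- function(schedule, t, horizon) {
  ends <- c(schedule$time_h[-1], horizon)
  vapply(t, function(tt) {
    sum(pmax(pmin(tt, ends) - schedule$time_h, 0) * schedule$rate_mL_per_h)
  }, numeric(1))
}
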