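# Shared fixtures built in code: small landscapes, an empty trap layout,
# and a scenario-scale parameter set.

empty_traps <- function() {
  data.frame(trap_id = character(0), x_m = numeric(0), y_m = numeric(0),
             active_from = as.Date(character(0)), lure = character(0),
             stringsAsFactors = FALSE)
}

scenario_params <- function(...) {
  sim_params(area_ha = 100, rect_width_m = 1000, rect_height_m = 1000, ...)
}

# population with hand-set interaction probabilities (bypasses the Beta draw
# while keeping a valid lure spec for the encounter model's mu0)
fixed_pint_population <- function(n, rectangle, pint, mu0 = 0.3,
                                  lure_name = "A", seed = 1) {
  pop <- init_population(n, rectangle,
                         lure_spec(lure_name, mu0, 0.5 * mu0 * (1 - mu0)),
                         seed = seed)
  pop$pint[, 1] <- pint
  pop
}

# conservation identity of a simulation: N0 + births = alive + deaths + capt
expect_conserved <- function(sim) {
  n <- sim$nightly
  lhs <- sim$n0 + cumsum(n$births)
  rhs <- n$n_alive + cumsum(n$deaths) + cumsum(n$captures)
  expect_equal(lhs, rhs)
}
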