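test_that("no interaction means no captures, certain interaction means all", {
  p <- scenario_params()
  # traps sitting exactly on every home-range centre, tiny mu0 so the
  # encounter probability at distance zero clamps to one
  pop <- fixed_pint_population(20, c(1000, 1000), pint = 0, mu0 = 0.01,
                               seed = 2)
  traps <- data.frame(trap_id = sprintf("T%02d", 1:20), x_m = pop$hx,
                      y_m = pop$hy, active_from = p$t0, lure = "A")
  set.seed(1)
  res <- nightly_captures(pop, traps, c(A = 1), p, date = p$t0, night = 1L)
  expect_length(res$captured, 0)
  expect_true(all(res$population$alive))

  pop$pint[, 1] <- 1
  set.seed(1)
  res <- nightly_captures(pop, traps, c(A = 1), p, date = p$t0, night = 1L)
  expect_length(res$captured, 20)
  expect_true(all(!res$population$alive))
  expect_true(all(res$population$capture_night == 1L))
})

test_that("nightly capture frequency equals p_enc * p_int", {
  # all individuals on top of a single trap; area chosen so D = 1 ha^-1,
  # hence sigma = 73.7 m, and mu0 set so p_enc(0) = g0/mu0 = 0.4 exactly
  n <- 1e4
  g0 <- g0_from_sigma(sigma_from_density(1))
  mu0 <- g0 / 0.4
  p <- sim_params(area_ha = n, rect_width_m = 1000, rect_height_m = 1000)
  pop <- fixed_pint_population(n, c(1000, 1000), pint = 0.5, mu0 = mu0,
                               seed = 3)
  pop$hx <- rep(500, n); pop$hy <- rep(500, n)
  traps <- data.frame(trap_id = "T1", x_m = 500, y_m = 500,
                      active_from = p$t0, lure = "A")
  set.seed(4)
  res <- nightly_captures(pop, traps, c(A = 1), p, date = p$t0, night = 1L)
  freq <- length(res$captured) / n
  expect_lt(abs(freq - 0.2), 3 * sqrt(0.2 * 0.8 / n))  # 0.012
})

test_that("a 50/50 mix of two identical lures behaves like a single lure", {
  n <- 5e3
  g0 <- g0_from_sigma(sigma_from_density(1))
  mu0 <- g0 / 0.4
  p <- sim_params(area_ha = n, rect_width_m = 1000, rect_height_m = 1000)
  pop <- init_population(n, c(1000, 1000),
                         list(lure_spec("A", mu0, mu0 * (1 - mu0) / 2),
                              lure_spec("B", mu0, mu0 * (1 - mu0) / 2)),
                         seed = 5)
  pop$pint[, 1] <- 0.5
  pop$pint[, 2] <- pop$pint[, 1]  # perfectly correlated
  pop$hx <- rep(500, n); pop$hy <- rep(500, n)
  traps <- data.frame(trap_id = "T1", x_m = 500, y_m = 500,
                      active_from = p$t0, lure = "A")
  set.seed(6)
  res <- nightly_captures(pop, traps, c(A = 0.5, B = 0.5), p,
                          date = p$t0, night = 1L)
  freq <- length(res$captured) / n
  expect_lt(abs(freq - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("lure mixes are validated", {
  p <- scenario_params()
  pop <- init_population(5, c(1000, 1000), lure_spec("A", 0.3, 0.1),
                         seed = 1)
  traps <- make_square_grid(100, 100)
  expect_error(nightly_captures(pop, traps, c(A = 0.6, B = 0.4), p),
               "unknown lure")
  expect_error(nightly_captures(pop, traps, c(A = 0.7), p), "sum")
})

test_that("the daily step conserves individuals and respects a zero death rate", {
  # negligible mortality, no traps, far from the breeding season:
  # the population must not change
  p <- sim_params(lifespan_yr = 1e9, t0 = as.Date("2021-10-01"),
                  t_end = as.Date("2021-10-31"))
  pop <- init_population(80, c(1160, 1660), lure_spec("A", 0.3, 0.1),
                         seed = 7)
  sim <- run_simulation(pop, empty_traps(), p, seed = 8)
  expect_true(all(sim$nightly$n_alive == 80))
  expect_equal(sum(sim$nightly$births), 0)
  expect_equal(sum(sim$nightly$deaths), 0)

  # conservation under the full process (both engines)
  p2 <- scenario_params()
  traps <- make_square_grid(100, 100)
  for (eng in c("cpp", "r")) {
    pop <- init_population(60, c(1000, 1000), lure_spec("A", 0.4, 0.15),
                           seed = 9)
    sim <- run_simulation(pop, traps, p2, seed = 10, engine = eng)
    expect_conserved(sim)
    expect_true(all(diff(cumsum(sim$nightly$captures)) >= 0))
  }
})

test_that("identical seeds give bitwise-identical simulations", {
  p <- scenario_params()
  traps <- make_square_grid(100, 100)
  run <- function(eng) {
    pop <- init_population(50, c(1000, 1000), lure_spec("A", 0.3, 0.1),
                           seed = 21)
    run_simulation(pop, traps, p, seed = 22, engine = eng)
  }
  for (eng in c("cpp", "r")) {
    a <- run(eng); b <- run(eng)
    expect_identical(a$nightly, b$nightly)
    expect_identical(capture_series(a, p$t0 + c(30, 90, 200)),
                     capture_series(b, p$t0 + c(30, 90, 200)))
  }
})

test_that("compiled and reference engines agree statistically", {
  p <- sim_params(area_ha = 100, rect_width_m = 1000, rect_height_m = 1000,
                  t0 = as.Date("2021-06-01"), t_end = as.Date("2021-08-31"))
  traps <- make_square_grid(100, 100)
  tot <- function(eng, seed) {
    pop <- init_population(40, c(1000, 1000), lure_spec("A", 0.3, 0.1),
                           seed = seed)
    sum(run_simulation(pop, traps, p, engine = eng)$nightly$captures)
  }
  a <- vapply(1:15, function(s) tot("cpp", s), numeric(1))
  b <- vapply(1:15, function(s) tot("r", s), numeric(1))
  se <- sqrt(stats::var(a) / 15 + stats::var(b) / 15)
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-9)
})

test_that("kill-trapping selects against trappable individuals", {
  p <- scenario_params()
  traps <- make_square_grid(100, 100)
  for (s in 1:5) {
    pop <- init_population(100, c(1000, 1000), lure_spec("A", 0.3, 0.1),
                           seed = s)
    mu_init <- mean(pop$pint[, 1])
    sim <- run_simulation(pop, traps, p, seed = 100 + s)
    surv <- sim$population$alive
    if (sum(sim$nightly$captures) > 0 && any(surv)) {
      expect_lt(mean(sim$population$pint[surv, 1]), mu_init)
    }
  }
})

test_that("catch-rate trigger follows the trailing-mean rule", {
  # initial rate 10/night; trailing mean 2 at night 14: ratio 0.2 <= 1-rc
  expect_equal(catch_rate_trigger(c(rep(10, 7), rep(2, 7)), rc = 0.8), 14L)
  # trailing mean 2.1: ratio 0.21 stays above the threshold
  expect_true(is.na(catch_rate_trigger(c(rep(10, 7), rep(2.1, 7)),
                                       rc = 0.8)))
  # constant catch rate never triggers
  expect_true(is.na(catch_rate_trigger(rep(5, 60), rc = 0.8)))
  # zero initial rate: fires immediately at night 8
  expect_equal(catch_rate_trigger(rep(0, 20), rc = 0.5), 8L)
  expect_error(catch_rate_trigger(rep(1, 20), rc = 1.5), "rc")
})

test_that("switch-mode simulations switch at the night the trigger rule gives", {
  p <- scenario_params()
  traps <- make_square_grid(100, 100)
  found <- 0L
  for (s in 1:6) {
    pop <- init_population(150, c(1000, 1000),
                           list(lure_spec("A", 0.3, 0.1),
                                lure_spec("B", 0.3, 0.1)), seed = s)
    sim <- run_simulation(pop, traps, p, mode = "switch", rc = 0.8,
                          seed = 50 + s)
    if (!is.na(sim$switch_night)) {
      found <- found + 1L
      expect_equal(sim$switch_night,
                   catch_rate_trigger(sim$nightly$captures, rc = 0.8))
    }
  }
  expect_gt(found, 0L)  # the trigger does fire under these conditions
})

test_that("run_simulation validates its configuration", {
  pop <- init_population(5, c(1000, 1000), lure_spec("A", 0.3, 0.1),
                         seed = 1)
  traps <- make_square_grid(100, 100)
  expect_error(run_simulation(pop, traps, scenario_params(),
                              mode = "simultaneous"), "two")
  pop2 <- init_population(5, c(1000, 1000),
                          list(lure_spec("A", 0.3, 0.1),
                               lure_spec("B", 0.3, 0.1)), seed = 1)
  expect_error(run_simulation(pop2, traps, scenario_params(),
                              mode = "switch"), "rc")
  expect_error(sim_params(t0 = as.Date("2022-01-01"),
                          t_end = as.Date("2021-06-01")), "after")
})
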