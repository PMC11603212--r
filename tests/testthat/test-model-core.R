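test_that("seasonal reproduction density is a renormalised truncated normal", {
  p <- sim_params()
  # peak at 1 April (day-of-year 91)
  grid <- 0:365
  expect_equal(grid[which.max(season_pdf(grid, p))], 91)
  # integrates to one over the year
  expect_equal(stats::integrate(season_pdf, 0, 365, params = p)$value, 1,
               tolerance = 1e-6)
  # one-sd ratio is the Gaussian identity (truncation factor cancels)
  expect_equal(season_pdf(91 + 20, p) / season_pdf(91, p), exp(-0.5),
               tolerance = 1e-9)
  expect_error(season_pdf(-1, p), "day-of-year")
  expect_error(season_pdf(366, p), "day-of-year")
})

test_that("mortality rate is the reciprocal lifespan", {
  expect_equal(mortality_rate(13), 1 / 13)
  expect_equal(mortality_rate(1), 1)
  expect_equal(mortality_rate(2), 0.5)
  expect_error(mortality_rate(0), "positive")
  expect_error(mortality_rate(-3), "positive")
})

test_that("density coefficient enforces the carrying-capacity equilibrium", {
  m <- 1 / 13
  cc <- density_coefficient(0.77, m, 175, 9)
  expect_equal(cc, (0.77 - m) / (175 * 9))
  expect_equal(cc, 4.401e-4, tolerance = 1e-3)
  # algebraic identity alpha - c * A * K = M, to machine precision
  expect_equal(0.77 - cc * 175 * 9, m, tolerance = 1e-15)
  expect_equal(density_coefficient(m + 1, m, 1, 1), 1)
  expect_error(density_coefficient(0.05, 1 / 13, 175, 9), "persist")
})

test_that("birth rate is density-dependent, seasonal and clamped at zero", {
  p <- sim_params()
  r <- demographic_rates(p)
  n_eq <- p$area_ha * p$carrying_capacity
  # at the equilibrium adult count the birth rate equals M * f(t)
  expect_equal(birth_rate(91, n_eq, r, p),
               r$mortality_rate * season_pdf(91, p))
  # without density dependence it is alpha * f(t)
  r0 <- structure(list(mortality_rate = r$mortality_rate, density_coeff = 0),
                  class = "demographic_rates")
  expect_equal(birth_rate(120, 500, r0, p),
               p$birth_rate_max * season_pdf(120, p))
  # clamped to zero at very high density
  expect_equal(birth_rate(91, 10 * n_eq, r, p), 0)
  expect_error(birth_rate(91, -5, r, p), "non-negative")
})

test_that("sigma-density and g0-sigma power laws match their coefficients", {
  expect_equal(sigma_from_density(1), 73.7)
  expect_equal(sigma_from_density(9), 73.7 * 9^-0.4, tolerance = 1e-12)
  expect_equal(round(sigma_from_density(9), 1), 30.6)
  # cap at low density, including exactly zero
  expect_equal(sigma_from_density(0.001), 155)
  expect_equal(sigma_from_density(0), 155)
  expect_error(sigma_from_density(-1), "non-negative")

  expect_equal(g0_from_sigma(73.7), 5.67 * 73.7^-0.99, tolerance = 1e-12)
  expect_equal(g0_from_sigma(73.7), 0.0803, tolerance = 1e-3)
  expect_equal(g0_from_sigma(155), 0.0385, tolerance = 1e-3)
  # clamped to 1 where the raw law exceeds a probability
  expect_equal(g0_from_sigma(1), 1)
  expect_error(g0_from_sigma(0), "positive")
})

test_that("power laws are monotone decreasing before their caps", {
  d <- sort(stats::runif(50, 0.2, 20))
  expect_true(all(diff(sigma_from_density(d)) <= 0))
  s <- sort(stats::runif(50, 6, 155))
  expect_true(all(diff(g0_from_sigma(s)) <= 0))
})

test_that("home-range radius is 2.45 sigma", {
  expect_equal(home_range_radius(155), 379.75)
  expect_equal(round(home_range_radius(155)), 380)
  expect_equal(home_range_radius(0), 0)
  expect_equal(home_range_radius(100), 245)
})

test_that("single-trap encounter probability is half-normal and bounded", {
  expect_equal(p_encounter(0, g0 = 0.05, mu0 = 0.25, sigma_m = 30), 0.2)
  expect_lt(p_encounter(1e5, g0 = 0.05, mu0 = 0.25, sigma_m = 30), 1e-12)
  expect_equal(p_encounter(30, g0 = 0.05, mu0 = 0.25, sigma_m = 30),
               0.2 * exp(-0.5))
  # clamped when g0/mu0 exceeds one
  expect_equal(p_encounter(0, g0 = 0.5, mu0 = 0.05, sigma_m = 30), 1)
  expect_error(p_encounter(-1, 0.05, 0.25, 30), "non-negative")
  expect_error(p_encounter(10, 0.05, 0, 30), "mu0")
})

test_that("encounter probabilities stay in [0,1] and decrease with distance", {
  set.seed(42)
  for (i in 1:25) {
    g0 <- stats::runif(1, 0.01, 1)
    mu0 <- stats::runif(1, 0.05, 0.95)
    sg <- stats::runif(1, 10, 155)
    d <- sort(stats::runif(30, 0, 500))
    pe <- p_encounter(d, g0, mu0, sg)
    expect_true(all(pe >= 0 & pe <= 1))
    expect_true(all(diff(pe) <= 1e-12))
    pt <- p_encounter_total(d, g0, mu0, sg)
    expect_true(pt >= max(pe) - 1e-12 && pt <= 1)
  }
})

test_that("multi-trap encounter probability composes independent traps", {
  expect_equal(p_encounter_total(numeric(0), 0.05, 0.25, 30), 0)
  expect_equal(p_encounter_total(40, 0.05, 0.25, 30),
               p_encounter(40, 0.05, 0.25, 30))
  # two traps with p = 0.5 each: 1 - 0.25 = 0.75 (p = 0.5 at d = 0 when
  # g0/mu0 = 0.5)
  expect_equal(p_encounter_total(c(0, 0), g0 = 0.1, mu0 = 0.2, sigma_m = 30),
               0.75)
})

test_that("multi-trap encounter matches a Monte-Carlo oracle", {
  set.seed(7)
  nrep <- 2e4
  for (i in 1:5) {
    d <- stats::runif(sample(2:6, 1), 0, 250)
    sg <- stats::runif(1, 30, 155)
    g0 <- g0_from_sigma(sg)
    mu0 <- stats::runif(1, 0.1, 0.9)
    pe <- p_encounter(d, g0, mu0, sg)
    # simulate per-trap independent Bernoulli encounters
    hits <- matrix(stats::runif(nrep * length(d)), nrep) <
      matrix(pe, nrep, length(d), byrow = TRUE)
    phat <- mean(rowSums(hits) > 0)
    p <- p_encounter_total(d, g0, mu0, sg)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nrep) + 1e-12)
  }
})

test_that("Beta moment matching is exact and flags invalid moments", {
  expect_equal(beta_params_from_moments(0.5, 0.125),
               c(shape1 = 0.5, shape2 = 0.5))
  sh <- beta_params_from_moments(0.28, 0.14)
  expect_equal(unname(sh), c(0.1232, 0.3168), tolerance = 1e-10)
  expect_true(all(sh < 1))  # U-shaped
  # round-trip: moments of Beta(a, b) recover (mean, var) to 1e-12
  set.seed(3)
  for (i in 1:50) {
    m <- stats::runif(1, 0.02, 0.98)
    v <- stats::runif(1, 1e-4, 0.99) * m * (1 - m)
    sh <- beta_params_from_moments(m, v)
    a <- sh[["shape1"]]; b <- sh[["shape2"]]
    expect_equal(a / (a + b), m, tolerance = 1e-12)
    expect_equal(a * b / ((a + b)^2 * (a + b + 1)), v, tolerance = 1e-12)
  }
  expect_error(beta_params_from_moments(0.5, 0.25), "invalid moments")
  expect_error(beta_params_from_moments(1.2, 0.01), "mean")
})
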