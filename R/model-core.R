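#' Seasonal reproduction density
#'
#' Probability density of the reproduction season over the calendar year: a
#' normal density centred on the seasonal peak (1 April by default) with a
#' 20-day standard deviation, truncated to `[0, 365]` and renormalised so it
#' integrates to one over the year. Multiplying an annual per-capita birth
#' rate by this density spreads the year's births over the season and yields
#' a per-day rate.
#'
#' @param t Day-of-year, in `[0, 365]` (vectorised).
#' @param params A [sim_params()] object.
#' @return Density value(s) in d^-1.
#' @export
#' @examples
#' p <- sim_params()
#' season_pdf(91, p)            # seasonal peak, 1 April
#' integrate(season_pdf, 0, 365, params = p)$value  # 1
season_pdf <- function(t, params = sim_params()) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > 365)) {
    stop("season_pdf: 't' must be a day-of-year in [0, 365]", call. = FALSE)
  }
  mu <- params$season_peak_doy
  sd <- params$season_sd_days
  z <- stats::pnorm(365, mu, sd) - stats::pnorm(0, mu, sd)
  stats::dnorm(t, mu, sd) / z
}

#' Natural mortality rate
#'
#' Constant per-capita natural mortality `M = 1 / l`, with `l` the average
#' life expectancy in the absence of control.
#'
#' @param lifespan_yr Life expectancy in years (> 0).
#' @return Mortality rate in yr^-1.
#' @export
#' @examples
#' mortality_rate(13)  # 0.0769 yr^-1
mortality_rate <- function(lifespan_yr) {
  if (!is.numeric(lifespan_yr) || any(lifespan_yr <= 0)) {
    stop("mortality_rate: 'lifespan_yr' must be positive", call. = FALSE)
  }
  1 / lifespan_yr
}

#' Density-dependence coefficient of the birth rate
#'
#' Strength `c` of the density-dependent reduction of the per-capita birth
#' rate, chosen so that the population is at statistical equilibrium when the
#' adult count equals `A * K`: the condition `alpha - c * N* = M` at
#' `N* = A * K` gives `c = (alpha - M) / (A * K)`.
#'
#' @param alpha Maximum per-capita annual birth rate (yr^-1).
#' @param mortality Natural mortality rate `M` (yr^-1); see
#'   [mortality_rate()].
#' @param area_ha Study area `A` (ha).
#' @param carrying_capacity Carrying capacity `K` (ha^-1).
#' @return Coefficient `c` in yr^-1 per individual.
#' @export
#' @examples
#' density_coefficient(0.77, 1 / 13, 175, 9)  # 4.40e-4
density_coefficient <- function(alpha, mortality, area_ha, carrying_capacity) {
  if (area_ha <= 0 || carrying_capacity <= 0) {
    stop("density_coefficient: area and carrying capacity must be positive",
         call. = FALSE)
  }
  if (alpha <= mortality) {
    stop("density_coefficient: 'alpha' must exceed 'mortality' or the ",
         "population cannot persist", call. = FALSE)
  }
  (alpha - mortality) / (area_ha * carrying_capacity)
}

#' Demographic rates derived from the model constants
#'
#' Convenience bundle of the constant demographic rates implied by a
#' [sim_params()] object: natural mortality `M = 1/l` and the
#' density-dependence coefficient `c = (alpha - M) / (A K)`.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `"demographic_rates"` with elements
#'   `mortality_rate` (yr^-1) and `density_coeff` (yr^-1 per individual).
#' @export
demographic_rates <- function(params = sim_params()) {
  m <- mortality_rate(params$lifespan_yr)
  cc <- density_coefficient(params$birth_rate_max, m, params$area_ha,
                            params$carrying_capacity)
  structure(list(mortality_rate = m, density_coeff = cc),
            class = "demographic_rates")
}

#' Per-capita daily birth rate
#'
#' Density-dependent seasonal birth rate
#' `B(t) = max(0, alpha - c * N*) * f(t)`, where `N*` is the number of live
#' adults recorded at the most recent onset of the reproduction season and
#' `f(t)` is the [season_pdf()]. Because `f` integrates to one over the year
#' (units d^-1), the product is already a per-day rate; the daily birth
#' probability used in the simulation's binomial draw is
#' `B(t) * dt_days`. Negative values of `alpha - c N*` (very high density)
#' are clamped to zero.
#'
#' @param t Day-of-year.
#' @param n_star Adult count at the last reproduction-season onset.
#' @param rates A [demographic_rates()] object.
#' @param params A [sim_params()] object.
#' @return Per-capita birth rate in d^-1.
#' @export
#' @examples
#' p <- sim_params()
#' r <- demographic_rates(p)
#' # at the equilibrium adult count A*K the annual birth rate equals M:
#' birth_rate(91, p$area_ha * p$carrying_capacity, r, p)
#' r$mortality_rate * season_pdf(91, p)  # identical
birth_rate <- function(t, n_star, rates, params = sim_params()) {
  if (any(n_star < 0)) {
    stop("birth_rate: 'n_star' must be non-negative", call. = FALSE)
  }
  pmax(0, params$birth_rate_max - rates$density_coeff * n_star) *
    season_pdf(t, params)
}

#' Home-range spatial decay parameter from population density
#'
#' Inverse power-law relationship between the spatial decay parameter `sigma`
#' of the half-normal home-range utilisation model and the population density
#' `D` (ha^-1): `sigma(D) = 73.7 * D^-0.4` m, capped at `sigma_max_m`
#' (155 m). At zero density the cap is returned.
#'
#' @param density Population density in possums ha^-1 (>= 0, vectorised).
#' @param params A [sim_params()] object.
#' @return `sigma` in metres.
#' @export
#' @examples
#' sigma_from_density(1)  # 73.7 m
#' sigma_from_density(9)  # 30.6 m
sigma_from_density <- function(density, params = sim_params()) {
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("sigma_from_density: 'density' must be non-negative", call. = FALSE)
  }
  out <- rep(params$sigma_max_m, length(density))
  pos <- density > 0
  out[pos] <- pmin(params$sigma_coeff * density[pos]^params$sigma_exp,
                   params$sigma_max_m)
  out
}

#' Nightly capture probability at the home-range centre
#'
#' Inverse power law between `g0`, the average nightly probability of capture
#' at the home-range centre, and the spatial decay parameter `sigma`:
#' `g0(sigma) = 5.67 * sigma^-0.99` (sigma in m). Animals with larger home
#' ranges spend less time near any one point, so `g0` falls with `sigma`.
#' The raw law exceeds one for `sigma` below about 5.8 m, so the result is
#' clamped to `[0, 1]` (it is a probability).
#'
#' @param sigma_m Spatial decay parameter in metres (> 0, vectorised).
#' @param params A [sim_params()] object.
#' @return `g0`, a nightly probability.
#' @export
#' @examples
#' g0_from_sigma(73.7)  # 0.080
#' g0_from_sigma(155)   # 0.039
g0_from_sigma <- function(sigma_m, params = sim_params()) {
  if (any(!is.finite(sigma_m)) || any(sigma_m <= 0)) {
    stop("g0_from_sigma: 'sigma_m' must be positive", call. = FALSE)
  }
  pmin(1, params$g0_coeff * sigma_m^params$g0_exp)
}

#' Home-range radius
#'
#' Radius of the circle containing 95% of an individual's space use under a
#' symmetric bivariate-normal utilisation model with scale `sigma`:
#' `r = 2.45 * sigma`.
#'
#' @param sigma_m Spatial decay parameter in metres (>= 0, vectorised).
#' @return Radius in metres.
#' @export
#' @examples
#' home_range_radius(155)  # 380 m (maximum home-range radius)
home_range_radius <- function(sigma_m) {
  if (any(!is.finite(sigma_m)) || any(sigma_m < 0)) {
    stop("home_range_radius: 'sigma_m' must be non-negative", call. = FALSE)
  }
  2.45 * sigma_m
}

#' Nightly probability of encountering a single trap
#'
#' Half-normal encounter model: the probability that an individual encounters
#' a device at distance `d` from its home-range centre in one night is
#' `p_enc(d) = (g0 / mu0) * exp(-d^2 / (2 sigma^2))`, where `g0` is the
#' average nightly capture probability at the centre and `mu0` the
#' population-mean interaction probability (capture = encounter x
#' interaction, so dividing by `mu0` recovers the encounter component). The
#' ratio `g0 / mu0` can exceed one for small `mu0`; the result is clamped to
#' `[0, 1]`.
#'
#' @param d Distance(s) to the trap in metres (>= 0).
#' @param g0 Nightly capture probability at the home-range centre.
#' @param mu0 Population-mean interaction probability, in (0, 1).
#' @param sigma_m Spatial decay parameter in metres (> 0).
#' @return Encounter probability in `[0, 1]`.
#' @export
#' @examples
#' p_encounter(0, g0 = 0.05, mu0 = 0.25, sigma_m = 30)   # 0.2
#' p_encounter(30, g0 = 0.05, mu0 = 0.25, sigma_m = 30)  # 0.2 * exp(-0.5)
p_encounter <- function(d, g0, mu0, sigma_m) {
  if (any(d < 0)) {
    stop("p_encounter: distances must be non-negative", call. = FALSE)
  }
  if (!is.numeric(mu0) || mu0 <= 0 || mu0 >= 1) {
    stop("p_encounter: 'mu0' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (g0 <= 0 || sigma_m <= 0) {
    stop("p_encounter: 'g0' and 'sigma_m' must be positive", call. = FALSE)
  }
  pmin(1, (g0 / mu0) * exp(-d^2 / (2 * sigma_m^2)))
}

#' Nightly probability of encountering at least one trap
#'
#' Complement of the product of per-trap non-encounter probabilities:
#' `p_encTOT = 1 - prod_j (1 - p_enc(d_j))`, treating per-trap encounters as
#' independent. An empty distance vector (no traps in the home range) gives
#' zero.
#'
#' @param distances Numeric vector of distances (m) to the traps within the
#'   home range; may be empty.
#' @inheritParams p_encounter
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' p_encounter_total(c(0, 50, 120), g0 = 0.08, mu0 = 0.28, sigma_m = 70)
p_encounter_total <- function(distances, g0, mu0, sigma_m) {
  if (length(distances) == 0L) {
    return(0)
  }
  1 - prod(1 - p_encounter(distances, g0, mu0, sigma_m))
}

#' Beta shape parameters from mean and variance
#'
#' Moment-matching parameterisation of the Beta distribution: for mean `mu`
#' and variance `s2` with `0 < s2 < mu (1 - mu)`, the shapes are
#' `a = mu * nu`, `b = (1 - mu) * nu` with `nu = mu (1 - mu) / s2 - 1`.
#' When both shapes are below one the distribution is U-shaped: most mass
#' sits near 0 (trap-shy) and near 1 (highly trappable).
#'
#' @param mean Mean in (0, 1).
#' @param variance Variance in `(0, mean * (1 - mean))`.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
#' @examples
#' beta_params_from_moments(0.5, 0.125)   # Beta(0.5, 0.5)
#' beta_params_from_moments(0.28, 0.14)   # both shapes < 1: U-shaped
beta_params_from_moments <- function(mean, variance) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("beta_params_from_moments: 'mean' must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(variance) || variance <= 0 ||
      variance >= mean * (1 - mean)) {
    stop("beta_params_from_moments: invalid moments; need 0 < variance < ",
         "mean * (1 - mean)", call. = FALSE)
  }
  nu <- mean * (1 - mean) / variance - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}
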