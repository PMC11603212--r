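#' Demographic and spatial constants of the trapping model
#'
#' Bundles every constant used by the individual-based simulation: landscape
#' geometry, possum demography, the density--home-range power laws and the
#' simulation calendar. Defaults are the values used for fitting the model to
#' a New Zealand forest-reserve kill-trapping operation: a 175 ha study area
#' represented as a 1160 m x 1660 m rectangle, carrying capacity 9 possums
#' ha^-1, 13-year lifespan, maximum annual per-capita birth rate 0.77, a
#' reproduction season peaking on 1 April (day-of-year 91) with a 20-day
#' standard deviation, and an 8-month trapping window from 1 June to the
#' following 31 January.
#'
#' @param area_ha Study area `A` in hectares, the normaliser for population
#'   density `D = N / A`.
#' @param rect_width_m,rect_height_m Extent (m) of the rectangle on which
#'   home-range centres are placed, origin at the south-west corner. The
#'   default 1160 x 1660 m rectangle encompasses the field trap layout with a
#'   100 m buffer.
#' @param trap_spacing_m Square trap-grid spacing `d_traps` (m) used for
#'   generic scenario landscapes.
#' @param carrying_capacity Carrying capacity `K` (possums ha^-1).
#' @param lifespan_yr Average life expectancy `l` (years) in the absence of
#'   control; natural mortality is `M = 1/l` per year.
#' @param birth_rate_max Maximum per-capita annual birth rate `alpha` (yr^-1).
#' @param season_peak_doy Day-of-year of the reproduction-season peak.
#' @param season_sd_days Standard deviation (days) of the seasonal birth pulse.
#' @param repro_onset_monthday Month-day (`"MM-DD"`) at which the adult count
#'   `N*` entering the density-dependent birth rate is (re)recorded; the start
#'   of the reproduction season, 1 February.
#' @param sigma_max_m Cap (m) on the home-range spatial decay parameter
#'   `sigma`; 155 m corresponds to a maximum home-range radius of
#'   `2.45 * 155 = 380` m.
#' @param sigma_coeff,sigma_exp Coefficients of the density--sigma power law
#'   `sigma(D) = sigma_coeff * D^sigma_exp` (D in ha^-1, sigma in m).
#' @param g0_coeff,g0_exp Coefficients of the sigma--g0 power law
#'   `g0(sigma) = g0_coeff * sigma^g0_exp` (sigma in m).
#' @param perception_distance_m Trap perception distance (m), used only to pad
#'   the trap-inclusion radius around the home range (see
#'   [traps_in_range()]); set to 0 for the strict unpadded radius.
#' @param dt_days Time step (days). The model is defined for nightly steps;
#'   values other than 1 scale the daily demographic probabilities.
#' @param t0,t_end First and last day of trapping (`Date`).
#'
#' @return An object of class `"sim_params"`: a named list of validated
#'   constants.
#' @seealso [demographic_rates()], [sigma_from_density()], [run_simulation()]
#' @export
#' @examples
#' p <- sim_params()
#' p$carrying_capacity * p$area_ha  # equilibrium adult population, 1575
sim_params <- function(area_ha = 175,
                       rect_width_m = 1160,
                       rect_height_m = 1660,
                       trap_spacing_m = 100,
                       carrying_capacity = 9,
                       lifespan_yr = 13,
                       birth_rate_max = 0.77,
                       season_peak_doy = 91,
                       season_sd_days = 20,
                       repro_onset_monthday = "02-01",
                       sigma_max_m = 155,
                       sigma_coeff = 73.7,
                       sigma_exp = -0.4,
                       g0_coeff = 5.67,
                       g0_exp = -0.99,
                       perception_distance_m = 10,
                       dt_days = 1,
                       t0 = as.Date("2021-06-01"),
                       t_end = as.Date("2022-01-31")) {
  p <- list(
    area_ha = area_ha, rect_width_m = rect_width_m,
    rect_height_m = rect_height_m, trap_spacing_m = trap_spacing_m,
    carrying_capacity = carrying_capacity, lifespan_yr = lifespan_yr,
    birth_rate_max = birth_rate_max, season_peak_doy = season_peak_doy,
    season_sd_days = season_sd_days,
    repro_onset_monthday = repro_onset_monthday,
    sigma_max_m = sigma_max_m, sigma_coeff = sigma_coeff,
    sigma_exp = sigma_exp, g0_coeff = g0_coeff, g0_exp = g0_exp,
    perception_distance_m = perception_distance_m, dt_days = dt_days,
    t0 = as.Date(t0), t_end = as.Date(t_end)
  )
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  num_pos <- c("area_ha", "rect_width_m", "rect_height_m", "trap_spacing_m",
               "carrying_capacity", "lifespan_yr", "birth_rate_max",
               "season_sd_days", "sigma_max_m", "sigma_coeff", "g0_coeff",
               "dt_days")
  for (k in num_pos) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("sim_params: '", k, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (p$season_peak_doy < 0 || p$season_peak_doy > 365) {
    stop("sim_params: 'season_peak_doy' must lie in [0, 365]", call. = FALSE)
  }
  if (p$sigma_exp >= 0 || p$g0_exp >= 0) {
    stop("sim_params: power-law exponents must be negative (both laws are ",
         "decreasing)", call. = FALSE)
  }
  if (p$perception_distance_m < 0) {
    stop("sim_params: 'perception_distance_m' must be >= 0", call. = FALSE)
  }
  if (!grepl("^[0-1][0-9]-[0-3][0-9]$", p$repro_onset_monthday)) {
    stop("sim_params: 'repro_onset_monthday' must be \"MM-DD\"", call. = FALSE)
  }
  if (!inherits(p$t0, "Date") || !inherits(p$t_end, "Date")) {
    stop("sim_params: 't0' and 't_end' must be Dates", call. = FALSE)
  }
  if (p$t_end <= p$t0) {
    stop("sim_params: 't_end' must be after 't0'", call. = FALSE)
  }
  # the alpha > M requirement is checked where c is derived
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Individual-based trapping model parameters\n")
  cat(sprintf("  landscape: A = %g ha (%g x %g m), trap spacing %g m\n",
              x$area_ha, x$rect_width_m, x$rect_height_m, x$trap_spacing_m))
  cat(sprintf("  demography: K = %g ha^-1, lifespan %g yr, alpha = %g yr^-1\n",
              x$carrying_capacity, x$lifespan_yr, x$birth_rate_max))
  cat(sprintf("  season: peak doy %g, sd %g d; N* reset on %s\n",
              x$season_peak_doy, x$season_sd_days, x$repro_onset_monthday))
  cat(sprintf("  space use: sigma = %g * D^%g m (cap %g m), g0 = %g * sigma^%g\n",
              x$sigma_coeff, x$sigma_exp, x$sigma_max_m, x$g0_coeff, x$g0_exp))
  cat(sprintf("  calendar: %s to %s, dt = %g d\n",
              format(x$t0), format(x$t_end), x$dt_days))
  invisible(x)
}

#' Lure specification
#'
#' A lure is described by the first two moments of the Beta distribution from
#' which per-individual interaction probabilities (`p_int`) are drawn at
#' population initialisation: mean `mu0` and variance `s0^2`. The pair must be
#' a valid Beta moment pair, i.e. `0 < var < mean * (1 - mean)`.
#'
#' @param name Lure label (e.g. `"A"`).
#' @param mean_pint Mean interaction probability in (0, 1).
#' @param var_pint Variance of the interaction probability.
#' @return An object of class `"lure_spec"`.
#' @seealso [beta_params_from_moments()], [init_population()]
#' @export
#' @examples
#' lure_spec("A", 0.28, 0.14)
lure_spec <- function(name, mean_pint, var_pint) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("lure_spec: 'name' must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(mean_pint) || mean_pint <= 0 || mean_pint >= 1) {
    stop("lure_spec: 'mean_pint' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(var_pint) || var_pint <= 0 ||
      var_pint >= mean_pint * (1 - mean_pint)) {
    stop("lure_spec: 'var_pint' must lie in (0, mean*(1-mean)) for a valid ",
         "Beta distribution", call. = FALSE)
  }
  structure(list(name = name, mean_pint = mean_pint, var_pint = var_pint),
            class = "lure_spec")
}

#' @export
print.lure_spec <- function(x, ...) {
  sh <- beta_params_from_moments(x$mean_pint, x$var_pint)
  cat(sprintf("Lure \"%s\": p_int ~ Beta(%.4g, %.4g)  [mean %.3g, var %.3g]\n",
              x$name, sh[["shape1"]], sh[["shape2"]], x$mean_pint, x$var_pint))
  invisible(x)
}

#' Uniform prior bounds for ABC calibration
#'
#' Independent uniform priors on the trap-shyness Beta mean `mu0`, its
#' variance `s0^2`, and the initial population size `N0` (integer-uniform).
#' Defaults are the study priors: `mu0 ~ U(0.1, 0.9)`, `s0^2 ~ U(0.01, 0.2)`,
#' `N0 ~ U{140, ..., 280}` (left-bounded by the total number of captures
#' observed, right-bounded by double that number). Joint draws with
#' `s0^2 >= mu0 * (1 - mu0)` are invalid Beta moment pairs and are resampled
#' by [sample_prior()], which truncates the joint prior accordingly.
#'
#' @param mu0_bounds,s02_bounds,n0_bounds Length-2 numeric lower/upper bounds.
#' @return An object of class `"abc_prior"`.
#' @export
#' @examples
#' abc_prior()
abc_prior <- function(mu0_bounds = c(0.1, 0.9),
                      s02_bounds = c(0.01, 0.2),
                      n0_bounds = c(140, 280)) {
  chk <- function(b, nm, lo = -Inf, hi = Inf) {
    if (!is.numeric(b) || length(b) != 2L || b[1] >= b[2] ||
        b[1] < lo || b[2] > hi) {
      stop("abc_prior: '", nm, "' must be ordered bounds within [",
           lo, ", ", hi, "]", call. = FALSE)
    }
  }
  chk(mu0_bounds, "mu0_bounds", 0, 1)
  chk(s02_bounds, "s02_bounds", 0, 0.25)
  chk(n0_bounds, "n0_bounds", 1)
  # at least one valid (mu0, s02) pair must exist under truncation
  max_mv <- if (mu0_bounds[1] <= 0.5 && mu0_bounds[2] >= 0.5) {
    0.25
  } else {
    max(mu0_bounds * (1 - mu0_bounds))
  }
  if (s02_bounds[1] >= max_mv) {
    stop("abc_prior: bounds admit no valid Beta moment pair", call. = FALSE)
  }
  structure(list(mu0_bounds = as.numeric(mu0_bounds),
                 s02_bounds = as.numeric(s02_bounds),
                 n0_bounds = c(floor(n0_bounds[1]), floor(n0_bounds[2]))),
            class = "abc_prior")
}

#' @export
print.abc_prior <- function(x, ...) {
  cat(sprintf(paste0("ABC priors: mu0 ~ U(%g, %g), s0^2 ~ U(%g, %g), ",
                     "N0 ~ U{%d..%d}\n"),
              x$mu0_bounds[1], x$mu0_bounds[2], x$s02_bounds[1],
              x$s02_bounds[2], x$n0_bounds[1], x$n0_bounds[2]))
  cat("(joint draws violating s0^2 < mu0(1-mu0) are resampled)\n")
  invisible(x)
}
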