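#' One night of trap encounters and captures
#'
#' Reference (pure R) implementation of the nightly capture process. For each
#' live individual the probability of encountering at least one active trap,
#' `p_encTOT` ([p_encounter_total()]), is computed from the current
#' population density (which sets `sigma` and `g0`); an encounter is drawn as
#' a Bernoulli trial; on encounter a lure is sampled from `lure_mix`; and a
#' final Bernoulli trial with the individual's `p_int` for that lure decides
#' capture. Captured individuals are removed (kill-traps) and logged with the
#' night index.
#'
#' @param pop A [init_population()] object (its first lure's mean is the
#'   `mu0` entering the encounter model).
#' @param traps Trap layout data frame.
#' @param lure_mix Named numeric vector of per-encounter lure shares, summing
#'   to one; names must be lures present in `pop$pint`.
#' @param params A [sim_params()] object.
#' @param date Optional `Date` used to filter traps by `active_from`.
#' @param night Integer night index recorded for captures.
#' @return A list with elements `population` (updated), `captured` (integer
#'   indices of tonight's captures), `sigma_m` and `g0`.
#' @export
nightly_captures <- function(pop, traps, lure_mix, params = sim_params(),
                             date = NULL, night = NA_integer_) {
  if (abs(sum(lure_mix) - 1) > 1e-8 || any(lure_mix < 0)) {
    stop("nightly_captures: 'lure_mix' shares must be non-negative and sum ",
         "to 1", call. = FALSE)
  }
  if (!all(names(lure_mix) %in% colnames(pop$pint))) {
    stop("nightly_captures: unknown lure name in 'lure_mix'", call. = FALSE)
  }
  tr <- traps
  if (!is.null(date)) tr <- tr[tr$active_from <= as.Date(date), , drop = FALSE]
  n_alive <- sum(pop$alive)
  sigma <- sigma_from_density(n_alive / params$area_ha, params)
  g0 <- g0_from_sigma(sigma, params)
  captured <- integer(0)
  if (nrow(tr) > 0L && n_alive > 0L) {
    mu0 <- pop$lures[[1]]$mean_pint
    radius <- home_range_radius(sigma) + params$perception_distance_m
    idx <- which(pop$alive)
    ptot <- vapply(idx, function(i) {
      d2 <- (tr$x_m - pop$hx[i])^2 + (tr$y_m - pop$hy[i])^2
      d <- sqrt(d2[d2 <= radius^2])
      p_encounter_total(d, g0, mu0, sigma)
    }, numeric(1))
    enc <- idx[stats::runif(length(idx)) < ptot]
    if (length(enc) > 0L) {
      lure <- if (length(lure_mix) == 1L) {
        rep(names(lure_mix), length(enc))
      } else {
        sample(names(lure_mix), length(enc), replace = TRUE, prob = lure_mix)
      }
      pi <- pop$pint[cbind(enc, match(lure, colnames(pop$pint)))]
      captured <- enc[stats::runif(length(enc)) < pi]
      pop$alive[captured] <- FALSE
      pop$capture_night[captured] <- night
    }
  }
  list(population = pop, captured = captured, sigma_m = sigma, g0 = g0)
}

#' One daily step of the population model
#'
#' Reference (pure R) implementation of a full day: the adult census `N*` is
#' refreshed if the date is the reproduction-season onset; births are drawn
#' as `Binomial(adults, B(t) * dt)` and newborns placed uniformly with fresh
#' Beta-distributed `p_int` values; natural deaths are per-individual
#' Bernoulli trials at rate `M/365 * dt`; then [nightly_captures()] runs; and
#' finally everyone ages by `dt`. Juveniles mature into adults at 365 days.
#'
#' @param state A list with fields `pop` (population), `date` (the current
#'   night's `Date`), `night` (integer index) and `n_star` (adult count at
#'   the last season onset). Build the initial state as
#'   `list(pop = pop, date = params$t0, night = 1L, n_star = sum(pop$alive))`.
#' @inheritParams nightly_captures
#' @return The updated state, with extra fields `captures`, `births`,
#'   `deaths` holding the day's tallies.
#' @export
step_day <- function(state, traps, lure_mix, params = sim_params()) {
  pop <- state$pop
  adult <- pop$age_days >= 365L
  if (format(state$date, "%m-%d") == params$repro_onset_monthday) {
    state$n_star <- sum(pop$alive & adult)
  }
  rates <- demographic_rates(params)
  doy <- day_of_year(state$date)

  # births
  n_adults <- sum(pop$alive & adult)
  b <- min(1, birth_rate(doy, state$n_star, rates, params) * params$dt_days)
  nb <- if (n_adults > 0 && b > 0) stats::rbinom(1L, n_adults, b) else 0L
  if (nb > 0L) {
    pop$hx <- c(pop$hx, stats::runif(nb, 0, pop$rectangle[1]))
    pop$hy <- c(pop$hy, stats::runif(nb, 0, pop$rectangle[2]))
    newp <- vapply(pop$lures, function(lu) {
      sh <- beta_params_from_moments(lu$mean_pint, lu$var_pint)
      stats::rbeta(nb, sh[["shape1"]], sh[["shape2"]])
    }, numeric(nb))
    pop$pint <- rbind(pop$pint, matrix(newp, nrow = nb))
    pop$age_days <- c(pop$age_days, rep(0L, nb))
    pop$alive <- c(pop$alive, rep(TRUE, nb))
    pop$capture_night <- c(pop$capture_night, rep(NA_integer_, nb))
  }

  # natural deaths
  md <- rates$mortality_rate / 365 * params$dt_days
  n <- length(pop$alive)
  dies <- pop$alive & stats::runif(n) < md
  pop$alive[dies] <- FALSE

  # captures
  nc <- nightly_captures(pop, traps, lure_mix, params,
                         date = state$date, night = state$night)
  pop <- nc$population

  pop$age_days <- pop$age_days + as.integer(params$dt_days)
  state$pop <- pop
  state$date <- state$date + params$dt_days
  state$night <- state$night + 1L
  state$captures <- length(nc$captured)
  state$births <- nb
  state$deaths <- sum(dies)
  state
}

day_of_year <- function(dates) {
  pmin(as.POSIXlt(dates)$yday + 1, 365)
}

#' Run the trapping simulation over the full calendar
#'
#' Simulates the population from `params$t0` to `params$t_end` (one step per
#' night) and records nightly captures, births, deaths and the surviving
#' population. Three lure deployments are supported: a single lure
#' (`"single"`, the first lure of the population), both lures deployed
#' simultaneously (`"simultaneous"`; on each encounter the trap carries the
#' second lure with probability `share_new`), and a triggered switch
#' (`"switch"`: the first lure until the 7-night trailing mean catch rate
#' drops to `(1 - rc)` times the initial rate, then the second lure
#' permanently).
#'
#' The default engine is compiled (identical model, written for speed); the
#' `"r"` engine loops [step_day()] and is the readable reference. The two
#' engines draw random numbers in different orders, so they agree
#' statistically rather than run-for-run.
#'
#' @param pop A [init_population()] object. Modes other than `"single"`
#'   require at least two lures.
#' @param traps Trap layout data frame.
#' @param params A [sim_params()] object.
#' @param mode Lure deployment mode, see above.
#' @param rc Catch-rate drop fraction in (0, 1) for `"switch"` mode.
#' @param share_new Per-encounter share of the second lure in
#'   `"simultaneous"` mode (default 0.5).
#' @param seed Optional integer seed; `NULL` keeps the caller's RNG stream.
#' @param engine `"cpp"` (default) or `"r"`.
#' @param trigger_window Nights in the trailing-mean window (default 7).
#' @return An object of class `"trapshy_sim"`: list with `nightly` (data
#'   frame: `date`, `captures`, `births`, `deaths`, `n_alive`,
#'   `n_adults`), `population`
#'   (final state, including newborns), `switch_night` (`NA` if no switch),
#'   `n0`, `mode` and `params`.
#' @seealso [capture_series()], [catch_rate_trigger()]
#' @export
#' @examples
#' pop <- init_population(40, c(1000, 1000), lure_spec("A", 0.3, 0.1),
#'                        seed = 1)
#' traps <- make_square_grid(100, 100)
#' sim <- run_simulation(pop, traps, sim_params(area_ha = 100), seed = 2)
#' sum(sim$nightly$captures)
run_simulation <- function(pop, traps, params = sim_params(),
                           mode = c("single", "simultaneous", "switch"),
                           rc = NULL, share_new = 0.5, seed = NULL,
                           engine = c("cpp", "r"), trigger_window = 7L) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (params$t_end <= params$t0) {
    stop("run_simulation: 't_end' must be after 't0'", call. = FALSE)
  }
  if (mode != "single" && ncol(pop$pint) < 2L) {
    stop("run_simulation: mode '", mode, "' needs a population with two ",
         "lures", call. = FALSE)
  }
  if (mode == "switch") {
    if (is.null(rc) || rc <= 0 || rc >= 1) {
      stop("run_simulation: 'switch' mode needs rc in (0, 1)", call. = FALSE)
    }
  } else {
    rc <- 0
  }
  if (!is.null(seed)) set.seed(seed)

  dates <- seq(params$t0, params$t_end, by = "day")
  n_days <- length(dates)
  fvals <- season_pdf(day_of_year(dates), params)
  onset <- format(dates, "%m-%d") == params$repro_onset_monthday
  active_night <- as.integer(pmax(1, as.numeric(traps$active_from - params$t0)
                                  + 1))
  active_night[traps$active_from > params$t_end] <- n_days + 1L
  n0_alive <- sum(pop$alive)

  if (engine == "cpp") {
    rates <- demographic_rates(params)
    shapes <- vapply(pop$lures, function(lu) {
      beta_params_from_moments(lu$mean_pint, lu$var_pint)
    }, numeric(2))
    par <- list(area_ha = params$area_ha,
                birth_rate_max = params$birth_rate_max,
                density_coeff = rates$density_coeff,
                mortality_rate = rates$mortality_rate,
                mu0 = pop$lures[[1]]$mean_pint,
                sigma_coeff = params$sigma_coeff,
                sigma_exp = params$sigma_exp,
                sigma_max_m = params$sigma_max_m,
                g0_coeff = params$g0_coeff, g0_exp = params$g0_exp,
                hr_mult = 2.45,
                perception_distance_m = params$perception_distance_m,
                dt_days = params$dt_days, adult_age_days = 365L)
    mode_i <- match(mode, c("single", "simultaneous", "switch")) - 1L
    res <- .sim_engine_cpp(pop$hx, pop$hy, pop$pint,
                           as.integer(pop$age_days),
                           traps$x_m, traps$y_m, active_night,
                           n_days, fvals, onset, par, mode_i, rc,
                           as.integer(trigger_window), share_new,
                           shapes[1, ], shapes[2, ],
                           pop$rectangle[1], pop$rectangle[2],
                           isTRUE(attr(pop, "copy_lures")))
    final <- pop
    final$hx <- res$hx
    final$hy <- res$hy
    final$pint <- res$pint
    colnames(final$pint) <- colnames(pop$pint)
    final$age_days <- res$age_days
    final$alive <- res$alive
    final$capture_night <- res$capture_night
    nightly <- data.frame(date = dates, captures = res$captures,
                          births = res$births, deaths = res$deaths,
                          n_alive = res$n_alive, n_adults = res$n_adults)
    switch_night <- res$switch_night
  } else {
    state <- list(pop = pop, date = params$t0, night = 1L,
                  n_star = sum(pop$alive & pop$age_days >= 365L))
    lures <- colnames(pop$pint)
    capt <- births <- deaths <- nalive <- nadult <- integer(n_days)
    switched <- FALSE
    switch_night <- NA_integer_
    for (k in seq_len(n_days)) {
      mix <- switch(mode,
                    single = stats::setNames(1, lures[1]),
                    simultaneous = stats::setNames(c(1 - share_new, share_new),
                                                   lures[1:2]),
                    switch = if (switched) {
                      stats::setNames(1, lures[2])
                    } else {
                      stats::setNames(1, lures[1])
                    })
      state <- step_day(state, traps, mix, params)
      capt[k] <- state$captures
      births[k] <- state$births
      deaths[k] <- state$deaths
      nalive[k] <- sum(state$pop$alive)
      nadult[k] <- sum(state$pop$alive & state$pop$age_days >= 365L)
      if (mode == "switch" && !switched && k >= trigger_window + 1) {
        trig <- catch_rate_trigger(capt[1:k], rc, trigger_window)
        if (!is.na(trig)) {
          switched <- TRUE
          switch_night <- trig
        }
      }
    }
    final <- state$pop
    nightly <- data.frame(date = dates, captures = capt, births = births,
                          deaths = deaths, n_alive = nalive,
                          n_adults = nadult)
  }

  structure(list(nightly = nightly, population = final,
                 switch_night = switch_night, n0 = n0_alive,
                 mode = mode, rc = if (mode == "switch") rc else NA_real_,
                 params = params, engine = engine),
            class = "trapshy_sim")
}

#' @export
print.trapshy_sim <- function(x, ...) {
  cat(sprintf("Trapping simulation (%s lure mode, %s engine)\n",
              x$mode, x$engine))
  cat(sprintf("  %s to %s: %d nights, N0 = %d\n", format(x$params$t0),
              format(x$params$t_end), nrow(x$nightly), x$n0))
  cat(sprintf("  captures %d, births %d, natural deaths %d, survivors %d\n",
              sum(x$nightly$captures), sum(x$nightly$births),
              sum(x$nightly$deaths), sum(x$population$alive)))
  if (!is.na(x$switch_night)) {
    cat(sprintf("  lure switched after night %d (rc = %g)\n",
                x$switch_night, x$rc))
  }
  invisible(x)
}

#' Cumulative captures at observation dates
#'
#' Aggregates a simulation's nightly captures into the cumulative count at
#' each requested check date (all captures on nights up to and including the
#' date).
#'
#' @param sim A [run_simulation()] result.
#' @param dates Vector of `Date`s (check/observation dates).
#' @return Data frame with columns `date` and `cumulative_captures`.
#' @export
capture_series <- function(sim, dates) {
  dates <- as.Date(dates)
  cum <- c(0L, cumsum(sim$nightly$captures))
  idx <- findInterval(as.numeric(dates), as.numeric(sim$nightly$date))
  data.frame(date = dates, cumulative_captures = cum[idx + 1L])
}

#' Catch-rate drop trigger
#'
#' Detects the night on which the daily catch rate, averaged over a trailing
#' window of 7 nights (standard trapping practice), first drops to
#' `(1 - rc)` times the initial rate. The initial rate is the mean over the
#' first 7 nights, so the trigger can fire from night 8 onwards; if the
#' initial rate is zero the trigger fires immediately at night 8. The
#' trigger fires at most once.
#'
#' @param per_night_captures Integer vector of nightly capture totals.
#' @param rc Drop fraction in (0, 1); e.g. `rc = 0.8` fires when the
#'   trailing mean falls to 20% of the initial rate.
#' @param window Nights in both the baseline and the trailing mean
#'   (default 7).
#' @return The integer night index of the trigger, or `NA` if it never
#'   fires.
#' @export
#' @examples
#' catch_rate_trigger(c(10, 10, 10, 10, 10, 10, 10, 2, 2, 2, 2, 2, 2, 1),
#'                    rc = 0.8)
catch_rate_trigger <- function(per_night_captures, rc, window = 7L) {
  if (!is.numeric(rc) || rc <= 0 || rc >= 1) {
    stop("catch_rate_trigger: 'rc' must lie strictly in (0, 1)",
         call. = FALSE)
  }
  n <- length(per_night_captures)
  if (n < window + 1L) {
    return(NA_integer_)
  }
  init <- mean(per_night_captures[seq_len(window)])
  if (init == 0) {
    return(as.integer(window + 1L))
  }
  for (day in seq.int(window + 1L, n)) {
    trailing <- mean(per_night_captures[(day - window + 1L):day])
    # small tolerance so exact-threshold ratios are not lost to rounding
    if (trailing / init <= 1 - rc + 1e-12) {
      return(as.integer(day))
    }
  }
  NA_integer_
}
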