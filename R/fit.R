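#' Draw parameter triples from the prior
#'
#' Independent uniform draws of `(mu0, s0^2, N0)` within the prior bounds;
#' `N0` is integer-uniform. Triples for which `(mu0, s0^2)` is not a valid
#' Beta moment pair (`s0^2 >= mu0 (1 - mu0)`) are redrawn jointly until
#' valid, which truncates the joint prior (and slightly reweights the
#' marginals towards central `mu0`).
#'
#' @param n_draws Number of triples (>= 1).
#' @param prior An [abc_prior()] object.
#' @return Data frame with columns `mu0`, `s02`, `n0`.
#' @export
sample_prior <- function(n_draws, prior = abc_prior()) {
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("sample_prior: 'n_draws' must be >= 1", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  draw <- function(k) {
    data.frame(
      mu0 = stats::runif(k, prior$mu0_bounds[1], prior$mu0_bounds[2]),
      s02 = stats::runif(k, prior$s02_bounds[1], prior$s02_bounds[2]),
      n0 = as.integer(floor(stats::runif(k, prior$n0_bounds[1],
                                         prior$n0_bounds[2] + 1)))
    )
  }
  out <- draw(n_draws)
  for (it in seq_len(1000L)) {
    bad <- out$s02 >= out$mu0 * (1 - out$mu0)
    if (!any(bad)) {
      return(out)
    }
    out[bad, ] <- draw(sum(bad))
  }
  stop("sample_prior: could not draw valid Beta moment pairs; check the ",
       "prior bounds", call. = FALSE)
}

#' Discrepancy between simulated and observed capture series
#'
#' Mean squared difference of cumulative captures at the shared observation
#' timestamps: `f(x, y) = (1/n) * sum_t (x_t - y_t)^2`. Both series must
#' carry exactly the same set of dates.
#'
#' @param simulated,observed Data frames with columns `date` and
#'   `cumulative_captures`.
#' @return A single non-negative number; zero iff the series are identical.
#' @export
#' @examples
#' a <- data.frame(date = as.Date("2021-06-01") + c(7, 14),
#'                 cumulative_captures = c(1, 2))
#' b <- transform(a, cumulative_captures = c(0, 0))
#' discrepancy(a, b)  # (1 + 4) / 2 = 2.5
discrepancy <- function(simulated, observed) {
  ds <- as.Date(simulated$date)
  do <- as.Date(observed$date)
  if (length(ds) != length(do) || !setequal(ds, do)) {
    stop("discrepancy: the two series must share the same observation ",
         "dates", call. = FALSE)
  }
  x <- simulated$cumulative_captures[order(ds)]
  y <- observed$cumulative_captures[order(do)]
  mean((x - y)^2)
}

#' Rejection step of ABC
#'
#' Keeps the fraction of parameter draws with the smallest discrepancy:
#' exactly `ceiling(acceptance_fraction * n)` rows. Ties are broken by draw
#' order (earlier draws kept).
#'
#' @param samples Data frame with (at least) an `error` column, one row per
#'   prior draw, in draw order.
#' @param acceptance_fraction Fraction in (0, 1]; the study design keeps the
#'   1% best of 30,000 draws (300 accepted).
#' @return `samples` with a logical `accepted` column added.
#' @export
abc_reject <- function(samples, acceptance_fraction = 0.01) {
  if (is.null(samples) || nrow(samples) == 0L) {
    stop("abc_reject: empty sample set", call. = FALSE)
  }
  if (acceptance_fraction <= 0 || acceptance_fraction > 1) {
    stop("abc_reject: 'acceptance_fraction' must lie in (0, 1]",
         call. = FALSE)
  }
  n <- nrow(samples)
  k <- ceiling(acceptance_fraction * n)
  ord <- order(samples$error, seq_len(n))  # stable: earlier draws win ties
  samples$accepted <- FALSE
  samples$accepted[ord[seq_len(k)]] <- TRUE
  samples
}

#' Posterior summaries of accepted ABC samples
#'
#' Per-parameter median and equal-tailed 95% credible interval (2.5% and
#' 97.5% quantiles, linear interpolation of order statistics), plus the
#' best-fitting (minimum-error) triple.
#'
#' @param accepted Data frame of accepted samples with columns `mu0`, `s02`,
#'   `n0` and `error` (>= 3 rows).
#' @return A list with `table` (data frame: parameter, median, lo, hi, best)
#'   and `best` (the minimum-error row).
#' @export
posterior_summary <- function(accepted) {
  if (nrow(accepted) < 3L) {
    stop("posterior_summary: need at least 3 accepted samples", call. = FALSE)
  }
  pars <- c("mu0", "s02", "n0")
  best <- accepted[which.min(accepted$error), , drop = FALSE]
  tab <- data.frame(
    parameter = pars,
    median = vapply(pars, function(p) stats::median(accepted[[p]]),
                    numeric(1)),
    lo = vapply(pars, function(p) {
      unname(stats::quantile(accepted[[p]], 0.025))
    }, numeric(1)),
    hi = vapply(pars, function(p) {
      unname(stats::quantile(accepted[[p]], 0.975))
    }, numeric(1)),
    best = as.numeric(best[1, pars]),
    row.names = NULL
  )
  list(table = tab, best = best)
}

#' Calibrate the trapping model by rejection ABC
#'
#' Fits the three unknowns of the individual-based trapping model — the mean
#' `mu0` and variance `s0^2` of the Beta distribution of individual
#' interaction probabilities, and the initial population size `N0` — to an
#' observed capture time series. For each of `n_draws` prior draws the
#' forward model is simulated once over the trapping calendar with the given
#' trap layout, the simulated cumulative captures are compared with the
#' observations at the check dates by mean squared error
#' ([discrepancy()]), and the `accept` fraction of draws with the smallest
#' errors forms the approximate posterior.
#'
#' @param observed Data frame with columns `date` and `cumulative_captures`
#'   (see [read_captures()]); all dates must lie within
#'   `[params$t0, params$t_end]`.
#' @param traps Trap layout data frame (see [read_traps()],
#'   [make_staged_layout()]).
#' @param prior An [abc_prior()] object.
#' @param params A [sim_params()] object; also supplies the trapping
#'   calendar and the home-range rectangle.
#' @param n_draws Number of prior draws (study design: 30,000).
#' @param accept Acceptance fraction (study design: 0.01, i.e. the best 1%).
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param engine Simulation engine, `"cpp"` (default) or `"r"`.
#' @param posterior_file Optional path; when given the full posterior table
#'   (columns `mu0, s02, n0, error, accepted`) is written as CSV.
#' @param verbose Print progress every 1000 draws.
#' @return An object of class `"trapshy"`: list with `posterior` (all
#'   draws + `error` + `accepted`), `summary` (medians and 95% credible
#'   intervals), `best`, `observed`, `traps`, `prior`, `params`, `n_draws`,
#'   `accept`, `seed`. Methods: `print`, `summary`, `coef`, `plot`,
#'   `simulate`, `predict`, `residuals`.
#' @seealso [run_scenarios()] to feed the posterior into lure-strategy
#'   comparisons.
#' @export
#' @examples
#' study <- generate_study(seed = 1)
#' fit <- trapshy(study$captures, study$traps, n_draws = 50, seed = 2)
#' coef(fit)
trapshy <- function(observed, traps, prior = abc_prior(),
                    params = sim_params(), n_draws = 30000, accept = 0.01,
                    seed, engine = c("cpp", "r"), posterior_file = NULL,
                    verbose = FALSE) {
  engine <- match.arg(engine)
  if (missing(seed)) {
    stop("trapshy: 'seed' is mandatory for reproducibility", call. = FALSE)
  }
  obs_dates <- as.Date(observed$date)
  if (any(obs_dates < params$t0) || any(obs_dates > params$t_end)) {
    stop("trapshy: observation dates must lie within [t0, t_end]",
         call. = FALSE)
  }
  y <- observed$cumulative_captures[order(obs_dates)]
  obs_sorted <- data.frame(date = sort(obs_dates), cumulative_captures = y)

  set.seed(seed)
  draws <- sample_prior(n_draws, prior)
  rect <- c(params$rect_width_m, params$rect_height_m)
  err <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    pop <- init_population(draws$n0[i], rect,
                           lure_spec("A", draws$mu0[i], draws$s02[i]))
    sim <- run_simulation(pop, traps, params, mode = "single",
                          engine = engine)
    x <- capture_series(sim, obs_sorted$date)
    err[i] <- discrepancy(x, obs_sorted)
    if (verbose && i %% 1000L == 0L) {
      message("trapshy: ", i, "/", n_draws, " draws")
    }
  }
  draws$error <- err
  draws <- abc_reject(draws, accept)
  acc <- draws[draws$accepted, , drop = FALSE]
  summ <- posterior_summary(acc)

  if (!is.null(posterior_file)) {
    utils::write.csv(draws, posterior_file, row.names = FALSE)
  }

  structure(list(posterior = draws, accepted = acc, summary = summ$table,
                 best = summ$best, observed = obs_sorted, traps = traps,
                 prior = prior, params = params, n_draws = n_draws,
                 accept = accept, seed = seed, engine = engine,
                 call = match.call()),
            class = "trapshy")
}
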