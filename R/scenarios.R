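#' Moments of a secondary lure
#'
#' The secondary lure's interaction-probability distribution keeps the
#' primary variance but multiplies the mean (1 for a lure of equal
#' attractiveness, 2 for a doubly attractive one). Doubling can push the
#' mean to or past 1, so it is capped at `mean_cap`; if the variance then
#' violates Beta validity at the capped mean it is shrunk to 0.9 times the
#' validity bound. The caps preserve the "more attractive" ordering.
#'
#' @param mu0,s02 Primary-lure Beta moments.
#' @param multiplier Mean multiplier (>= 1).
#' @param mean_cap Upper cap on the secondary mean (default 0.95).
#' @return Named numeric vector `c(mean, var)`.
#' @export
secondary_lure_moments <- function(mu0, s02, multiplier, mean_cap = 0.95) {
  m <- min(multiplier * mu0, mean_cap)
  bound <- m * (1 - m)
  s2 <- if (s02 >= bound) 0.9 * bound else s02
  c(mean = m, var = s2)
}

#' Build the seven lure-deployment scenarios
#'
#' One baseline (single lure A for the whole operation) and six two-lure
#' strategies: lure B (same mean attractiveness as A) or lure C (double the
#' mean, same variance), each deployed either simultaneously with A (50/50
#' encounter shares from the start) or as a switch triggered when the
#' 7-night trailing catch rate drops by `rc` (80% or 90%).
#'
#' @param mu0,s02 Moments of the primary (lure A) interaction-probability
#'   Beta distribution; typically posterior medians, but [run_scenarios()]
#'   rebuilds the lures per replicate from each posterior draw using the
#'   scenario's `multiplier` field.
#' @param rc_values The two switch thresholds (default `c(0.8, 0.9)`).
#' @param mean_cap Cap applied to the secondary mean, see
#'   [secondary_lure_moments()].
#' @return A list of 7 `"scenario_spec"` objects with fields `name`, `mode`
#'   (`"single"`, `"simultaneous"` or `"switch"`), `rc` (`NA` unless a
#'   switch), `multiplier`, `mean_cap` and `lures` (list of [lure_spec()]s
#'   at the supplied moments).
#' @export
#' @examples
#' sc <- build_scenarios(0.28, 0.14)
#' vapply(sc, `[[`, character(1), "name")
build_scenarios <- function(mu0, s02, rc_values = c(0.8, 0.9),
                            mean_cap = 0.95) {
  stopifnot(length(rc_values) == 2L, all(rc_values > 0), all(rc_values < 1))
  spec <- function(name, mode, rc, multiplier, new_name) {
    lures <- list(lure_spec("A", mu0, s02))
    if (!is.na(multiplier)) {
      mo <- secondary_lure_moments(mu0, s02, multiplier, mean_cap)
      lures <- c(lures, list(lure_spec(new_name, mo[["mean"]], mo[["var"]])))
    }
    structure(list(name = name, mode = mode, rc = rc,
                   multiplier = multiplier, mean_cap = mean_cap,
                   lures = lures),
              class = "scenario_spec")
  }
  list(
    spec("A (baseline)", "single", NA_real_, NA_real_, NA_character_),
    spec("A+B simultaneous", "simultaneous", NA_real_, 1, "B"),
    spec(sprintf("A then B (rc=%g)", rc_values[1]), "switch", rc_values[1],
         1, "B"),
    spec(sprintf("A then B (rc=%g)", rc_values[2]), "switch", rc_values[2],
         1, "B"),
    spec("A+C simultaneous", "simultaneous", NA_real_, 2, "C"),
    spec(sprintf("A then C (rc=%g)", rc_values[1]), "switch", rc_values[1],
         2, "C"),
    spec(sprintf("A then C (rc=%g)", rc_values[2]), "switch", rc_values[2],
         2, "C")
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario \"%s\" (%s%s)\n", x$name, x$mode,
              if (!is.na(x$rc)) sprintf(", rc = %g", x$rc) else ""))
  for (lu in x$lures) print(lu)
  invisible(x)
}

#' Run lure-deployment scenarios against a posterior
#'
#' For each scenario and each of `n_reps` replicates: draw one accepted
#' parameter triple from the posterior (uniformly, with replacement),
#' initialise `N0` individuals on the scenario landscape (by default the
#' generic 100 ha square with a 100 m trap grid) with independent `p_int`
#' values per lure, simulate the 8-month trapping window, and record the
#' surviving population size, the survivors' mean `p_int` towards lure A,
#' and the night daily captures plateau ([plateau_day()]). Each scenario
#' reuses the same seed, so replicate `r` of every scenario sees the same
#' posterior draw and (for equal lure counts) the same initial population —
#' a paired design that sharpens between-scenario contrasts.
#'
#' @param posterior A [trapshy()] fit, or a data frame of accepted triples
#'   with columns `mu0`, `s02`, `n0`.
#' @param n_reps Replicates per scenario (study design: 10,000).
#' @param seed Integer seed (mandatory).
#' @param scenarios List of scenario specs; default [build_scenarios()] at
#'   the posterior medians (moments are rebuilt per draw regardless).
#' @param params A [sim_params()] object for the scenario landscape;
#'   defaults to the generic 100 ha square (`area_ha = 100`, 1000 x 1000 m
#'   rectangle).
#' @param traps Trap layout; default a 100 m square grid over the landscape.
#' @param plateau_eps Threshold fraction for [plateau_day()] (default 0.05).
#' @param correlated_lures If `TRUE`, the secondary lure's `p_int` values
#'   are set identical to lure A's (a degenerate mode in which a two-lure
#'   deployment should collapse to the baseline; used for model checking).
#' @param engine Simulation engine.
#' @return An object of class `"trapshy_scenarios"`: list with `results`
#'   (one row per scenario x replicate: `scenario`, `rep`, `mu0`, `s02`,
#'   `n0`, `survivors`, `mean_pint_A`, `plateau_day`, `switch_night`) and
#'   `summary` (see [scenario_table()]).
#' @export
#' @examples
#' post <- data.frame(mu0 = 0.3, s02 = 0.1, n0 = 150)
#' run_scenarios(post, n_reps = 3, seed = 1)
run_scenarios <- function(posterior, n_reps, seed, scenarios = NULL,
                          params = NULL, traps = NULL, plateau_eps = 0.05,
                          correlated_lures = FALSE,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (missing(seed)) {
    stop("run_scenarios: 'seed' is mandatory", call. = FALSE)
  }
  if (inherits(posterior, "trapshy")) posterior <- posterior$accepted
  if (nrow(posterior) == 0L) {
    stop("run_scenarios: empty posterior", call. = FALSE)
  }
  if (is.null(params)) {
    params <- sim_params(area_ha = 100, rect_width_m = 1000,
                         rect_height_m = 1000)
  }
  if (is.null(traps)) {
    traps <- make_square_grid(params$area_ha, params$trap_spacing_m,
                              t0 = params$t0)
  }
  if (is.null(scenarios)) {
    scenarios <- build_scenarios(stats::median(posterior$mu0),
                                 stats::median(posterior$s02))
  }
  rect <- c(params$rect_width_m, params$rect_height_m)
  res <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    set.seed(seed)  # paired streams across scenarios
    rows <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      tr <- posterior[sample.int(nrow(posterior), 1L), ]
      lures <- list(lure_spec("A", tr$mu0, tr$s02))
      if (!is.na(sc$multiplier)) {
        mo <- secondary_lure_moments(tr$mu0, tr$s02, sc$multiplier,
                                     sc$mean_cap)
        lures <- c(lures, list(
          lure_spec(sc$lures[[2]]$name, mo[["mean"]], mo[["var"]])))
      }
      pop <- init_population(tr$n0, rect, lures)
      if (correlated_lures && ncol(pop$pint) > 1L) {
        pop$pint[, 2L] <- pop$pint[, 1L]
        attr(pop, "copy_lures") <- TRUE
      }
      sim <- run_simulation(pop, traps, params, mode = sc$mode,
                            rc = if (is.na(sc$rc)) NULL else sc$rc,
                            engine = engine)
      surv <- sim$population$alive
      rows[[r]] <- data.frame(
        scenario = sc$name, rep = r, mu0 = tr$mu0, s02 = tr$s02,
        n0 = tr$n0, survivors = sum(surv),
        mean_pint_A = if (any(surv)) mean(sim$population$pint[surv, 1L])
                      else NA_real_,
        plateau_day = plateau_day(sim$nightly$captures, plateau_eps),
        switch_night = sim$switch_night
      )
    }
    res[[s]] <- do.call(rbind, rows)
  }
  results <- do.call(rbind, res)
  structure(list(results = results, summary = scenario_table(results),
                 scenarios = scenarios, n_reps = n_reps, seed = seed,
                 params = params, plateau_eps = plateau_eps),
            class = "trapshy_scenarios")
}

#' Summary table of scenario outcomes
#'
#' Per-scenario medians and equal-tailed 95% intervals over replicates of
#' the surviving population size and the survivors' mean `p_int` towards
#' lure A, plus the median capture-plateau night.
#'
#' @param results The `results` data frame of [run_scenarios()].
#' @return Data frame with one row per scenario: `scenario`,
#'   `survivors_median`, `survivors_lo`, `survivors_hi`,
#'   `mean_pint_A_median`, `mean_pint_A_lo`, `mean_pint_A_hi`,
#'   `plateau_day_median`, `n_reps`. Scenario order follows the input.
#' @export
scenario_table <- function(results) {
  q <- function(v, p) unname(stats::quantile(v, p, na.rm = TRUE))
  # counts summarised by order statistics (type 1) so medians stay integer
  qi <- function(v, p) {
    as.integer(unname(stats::quantile(v, p, na.rm = TRUE, type = 1)))
  }
  sc_names <- unique(results$scenario)
  out <- lapply(sc_names, function(nm) {
    r <- results[results$scenario == nm, ]
    data.frame(
      scenario = nm,
      survivors_median = qi(r$survivors, 0.5),
      survivors_lo = qi(r$survivors, 0.025),
      survivors_hi = qi(r$survivors, 0.975),
      mean_pint_A_median = stats::median(r$mean_pint_A, na.rm = TRUE),
      mean_pint_A_lo = q(r$mean_pint_A, 0.025),
      mean_pint_A_hi = q(r$mean_pint_A, 0.975),
      plateau_day_median = if (all(is.na(r$plateau_day))) NA_integer_
                           else qi(r$plateau_day, 0.5),
      n_reps = nrow(r)
    )
  })
  do.call(rbind, out)
}

#' @export
print.trapshy_scenarios <- function(x, digits = 4, ...) {
  cat(sprintf("Lure-strategy scenario runs: %d replicates each, seed %d\n",
              x$n_reps, x$seed))
  s <- x$summary
  cat(sprintf("  %-22s %18s %26s %8s\n", "scenario", "survivors",
              "mean p_int(A) survivors", "plateau"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-22s %4d [%4d, %4d]   %.4f [%.4f, %.4f]   %6s\n",
                s$scenario[i], s$survivors_median[i], s$survivors_lo[i],
                s$survivors_hi[i], s$mean_pint_A_median[i],
                s$mean_pint_A_lo[i], s$mean_pint_A_hi[i],
                ifelse(is.na(s$plateau_day_median[i]), "-",
                       format(s$plateau_day_median[i]))))
  }
  invisible(x)
}

#' Night on which daily captures plateau
#'
#' First night after which the 7-night trailing mean capture rate stays
#' below `epsilon_fraction` times the initial rate (mean of the first 7
#' nights) for the remainder of the run — the point at which the most
#' trappable individuals have been caught and captures level off.
#'
#' @param per_night_captures Integer vector of nightly capture totals.
#' @param epsilon_fraction Plateau threshold as a fraction of the initial
#'   rate, in (0, 1) (default 0.05).
#' @param window Trailing-window length in nights (default 7).
#' @return Integer night index, or `NA` if the rate never settles below the
#'   threshold (or the initial rate is zero).
#' @export
#' @examples
#' plateau_day(c(rep(5, 30), rep(0, 60)))
plateau_day <- function(per_night_captures, epsilon_fraction = 0.05,
                        window = 7L) {
  if (epsilon_fraction <= 0 || epsilon_fraction >= 1) {
    stop("plateau_day: 'epsilon_fraction' must lie strictly in (0, 1)",
         call. = FALSE)
  }
  n <- length(per_night_captures)
  if (n < window + 1L) {
    return(NA_integer_)
  }
  init <- mean(per_night_captures[seq_len(window)])
  if (init == 0) {
    return(NA_integer_)
  }
  trailing <- stats::filter(per_night_captures, rep(1 / window, window),
                            sides = 1)
  ok <- !is.na(trailing) & trailing < epsilon_fraction * init
  # first index from which 'ok' holds through the end of the run
  bad <- which(!ok[seq.int(window, n)]) + window - 1L
  if (length(bad) == 0L) {
    return(as.integer(window))
  }
  last_bad <- max(bad)
  if (last_bad >= n) {
    return(NA_integer_)
  }
  as.integer(last_bad + 1L)
}
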