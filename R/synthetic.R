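#' Square trap grid
#'
#' Regular square grid of traps covering a square study area, with traps at
#' 0, spacing, 2*spacing, ... on both axes (boundary inclusive), all active
#' from `t0`. A 100 ha area with 100 m spacing yields an 11 x 11 = 121-trap
#' lattice. If the spacing exceeds the side length the degenerate grid
#' contains the single origin trap (inclusive-origin convention).
#'
#' @param area_ha Area in hectares (> 0).
#' @param spacing_m Trap spacing in metres (> 0).
#' @param t0 Activation date for every trap.
#' @param lure Lure label recorded on the traps.
#' @return Trap layout data frame: `trap_id`, `x_m`, `y_m`, `active_from`,
#'   `lure`.
#' @export
#' @examples
#' nrow(make_square_grid(100, 100))  # 121
make_square_grid <- function(area_ha, spacing_m,
                             t0 = as.Date("2021-06-01"), lure = "A") {
  if (area_ha <= 0 || spacing_m <= 0) {
    stop("make_square_grid: area and spacing must be positive", call. = FALSE)
  }
  side <- sqrt(area_ha * 1e4)
  coords <- seq(0, side, by = spacing_m)
  g <- expand.grid(x_m = coords, y_m = coords)
  data.frame(trap_id = sprintf("T%03d", seq_len(nrow(g))),
             x_m = g$x_m, y_m = g$y_m,
             active_from = as.Date(t0), lure = lure,
             stringsAsFactors = FALSE)
}

#' Staged transect trap layout
#'
#' Synthetic layout emulating the structure of the field deployment: 105
#' kill-traps along transect polylines inside the 1160 x 1660 m fitting
#' rectangle, of which 66 are active from early May and the remaining 39
#' are added in two stages in mid June and mid July. Transects are straight
#' polylines with jittered trap spacing of 100-150 m; only the layout's
#' statistics (trap count, staging, extent), not the real trap positions,
#' are emulated.
#'
#' @param seed Integer seed for the layout randomness.
#' @param n_traps Total number of traps (default 105).
#' @param n_initial Number active from the start (default 66).
#' @param rect `c(width_m, height_m)` of the layout rectangle.
#' @param stage_dates Activation dates: initial traps, first addition,
#'   second addition.
#' @return Trap layout data frame (see [make_square_grid()]).
#' @export
#' @examples
#' tr <- make_staged_layout(seed = 1)
#' table(tr$active_from)
make_staged_layout <- function(seed, n_traps = 105L, n_initial = 66L,
                               rect = c(1160, 1660),
                               stage_dates = as.Date(c("2021-05-05",
                                                       "2021-06-15",
                                                       "2021-07-15"))) {
  set.seed(seed)
  n_transects <- 7L
  xs <- ys <- numeric(0)
  tindex <- 1L
  while (length(xs) < n_traps) {
    x0 <- (tindex - 0.5) / n_transects * rect[1] + stats::runif(1, -60, 60)
    y <- stats::runif(1, 30, 90)
    while (y < rect[2] - 30 && length(xs) < n_traps) {
      xs <- c(xs, min(max(x0 + stats::runif(1, -40, 40), 0), rect[1]))
      ys <- c(ys, y)
      y <- y + stats::runif(1, 100, 150)
    }
    tindex <- if (tindex == n_transects) 1L else tindex + 1L
  }
  active <- rep(stage_dates[1], n_traps)
  later <- sample.int(n_traps, n_traps - n_initial)
  half <- length(later) %/% 2L
  active[later[seq_len(half)]] <- stage_dates[2]
  active[later[seq.int(half + 1L, length(later))]] <- stage_dates[3]
  data.frame(trap_id = sprintf("T%03d", seq_len(n_traps)),
             x_m = xs, y_m = ys, active_from = active, lure = "A",
             stringsAsFactors = FALSE)
}

#' Trap-check schedule
#'
#' Observation dates emulating field practice: checks twice a week
#' (alternating 3- and 4-day gaps) for the first eight weeks, after which
#' the interval lengthens by a factor of 1.5 per month as catch rates fall,
#' capped at 28 days. Dates are strictly increasing and lie within
#' `(t0, t_end]`.
#'
#' @param t0,t_end Calendar bounds (`Date`); the first check falls 3 days
#'   after `t0`.
#' @param initial_interval Mean initial check interval in days
#'   (default 3.5, i.e. twice weekly).
#' @param growth Monthly interval growth factor after week 8 (default 1.5).
#' @param cap_days Maximum interval (default 28).
#' @return Vector of `Date`s.
#' @export
#' @examples
#' make_check_schedule()
make_check_schedule <- function(t0 = as.Date("2021-06-01"),
                                t_end = as.Date("2022-01-31"),
                                initial_interval = 3.5, growth = 1.5,
                                cap_days = 28) {
  if (t_end <= t0) {
    stop("make_check_schedule: 't_end' must be after 't0'", call. = FALSE)
  }
  offsets <- integer(0)
  d <- 0
  short <- TRUE  # alternate 3/4-day gaps in the twice-weekly phase
  while (TRUE) {
    gap <- if (d < 56) {
      g <- if (short) floor(initial_interval) else ceiling(initial_interval)
      short <- !short
      g
    } else {
      max(1, round(min(cap_days, initial_interval *
                                   growth^((d - 56) / 30.44))))
    }
    d <- d + gap
    if (d > as.numeric(t_end - t0)) break
    offsets <- c(offsets, d)
  }
  t0 + offsets
}

#' Generate a synthetic trapping study with known ground truth
#'
#' Forward-simulates the full model at a known parameter triple and records
#' the cumulative captures at a realistic check schedule, producing a
#' self-contained dataset on which the ABC calibration can be validated.
#' The default study emulates the field dataset's structure: the staged
#' 66-to-105-trap transect layout on the 1160 x 1660 m rectangle,
#' twice-weekly checks that lengthen over time, and a ground truth
#' `(mu0 = 0.3, s0^2 = 0.1, N0 = 200)` chosen inside the priors, which
#' yields on the order of 140 captures over the 8-month window.
#'
#' @param true_params List with elements `mu0`, `s02`, `n0`: the ground
#'   truth.
#' @param layout Trap layout; default [make_staged_layout()] drawn from the
#'   same seed.
#' @param schedule Check dates; default [make_check_schedule()] over the
#'   parameter calendar.
#' @param seed Integer seed (mandatory); the study is fully reproducible
#'   from it.
#' @param params A [sim_params()] object.
#' @param obs_noise_sd Standard deviation of optional Gaussian observation
#'   noise added to the cumulative counts (then rounded, floored at zero
#'   and made non-decreasing). Default 0: counts are exact, as for kill
#'   traps.
#' @return An object of class `"trapshy_study"`: list with `truth`,
#'   `traps`, `check_dates`, `captures` (data frame `date`,
#'   `cumulative_captures`), `nightly`, `seed` and `params`.
#' @export
#' @examples
#' st <- generate_study(seed = 42)
#' utils::tail(st$captures, 3)
generate_study <- function(true_params = list(mu0 = 0.3, s02 = 0.1,
                                              n0 = 200),
                           layout = NULL, schedule = NULL, seed,
                           params = sim_params(), obs_noise_sd = 0) {
  if (missing(seed)) {
    stop("generate_study: 'seed' is mandatory", call. = FALSE)
  }
  stopifnot(all(c("mu0", "s02", "n0") %in% names(true_params)))
  if (is.null(layout)) layout <- make_staged_layout(seed)
  if (is.null(schedule)) {
    schedule <- make_check_schedule(params$t0, params$t_end)
  }
  set.seed(seed)
  pop <- init_population(true_params$n0,
                         c(params$rect_width_m, params$rect_height_m),
                         lure_spec("A", true_params$mu0, true_params$s02))
  sim <- run_simulation(pop, layout, params, mode = "single")
  series <- capture_series(sim, schedule)
  if (obs_noise_sd > 0) {
    noisy <- series$cumulative_captures +
      stats::rnorm(nrow(series), 0, obs_noise_sd)
    series$cumulative_captures <- cummax(pmax(0, round(noisy)))
  }
  structure(list(truth = true_params, traps = layout,
                 check_dates = schedule, captures = series,
                 nightly = sim$nightly, seed = seed, params = params),
            class = "trapshy_study")
}

#' @export
print.trapshy_study <- function(x, ...) {
  cat("Synthetic trapping study\n")
  cat(sprintf("  truth: mu0 = %g, s0^2 = %g, N0 = %d (seed %d)\n",
              x$truth$mu0, x$truth$s02, x$truth$n0, x$seed))
  cat(sprintf("  %d traps (%d active initially), %d checks, %d captures\n",
              nrow(x$traps), sum(x$traps$active_from <= x$params$t0),
              length(x$check_dates),
              utils::tail(x$captures$cumulative_captures, 1)))
  invisible(x)
}
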