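#' Initialise a simulated population
#'
#' Places `n0` adult individuals uniformly at random on the study rectangle
#' and assigns each one an independent interaction probability `p_int` per
#' lure, drawn from that lure's Beta distribution (moment-matched via
#' [beta_params_from_moments()]). Draws for different lures are independent:
#' an individual can be shy towards one lure and attracted to another.
#'
#' @param n0 Initial number of adults (>= 0).
#' @param rectangle Numeric length-2 `c(width_m, height_m)`: the study
#'   rectangle `[0, width] x [0, height]`, origin at the south-west corner.
#' @param lures A [lure_spec()] or list of them; at least one.
#' @param seed Optional integer seed. If `NULL` (the default) the current RNG
#'   stream is used, so callers composing larger seeded pipelines keep a
#'   single stream.
#' @return An object of class `"trapshy_population"`: a list with fields
#'   `hx`, `hy` (home-range centres, m), `pint` (matrix, one column per
#'   lure), `age_days` (initial adults start at 10 years), `alive`,
#'   `capture_night` (integer night index, `NA` if never captured),
#'   `rectangle` and `lures`.
#' @export
#' @examples
#' pop <- init_population(50, c(1000, 1000), lure_spec("A", 0.3, 0.1),
#'                        seed = 1)
#' colMeans(pop$pint)
init_population <- function(n0, rectangle, lures, seed = NULL) {
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 0 || n0 != floor(n0)) {
    stop("init_population: 'n0' must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(rectangle) || length(rectangle) != 2L ||
      any(rectangle <= 0)) {
    stop("init_population: 'rectangle' must be c(width_m, height_m) > 0",
         call. = FALSE)
  }
  if (inherits(lures, "lure_spec")) lures <- list(lures)
  if (length(lures) == 0L ||
      !all(vapply(lures, inherits, logical(1), "lure_spec"))) {
    stop("init_population: 'lures' must be one or more lure_spec objects",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n0 <- as.integer(n0)
  pint <- matrix(NA_real_, nrow = n0, ncol = length(lures),
                 dimnames = list(NULL,
                                 vapply(lures, `[[`, character(1), "name")))
  hx <- stats::runif(n0, 0, rectangle[1])
  hy <- stats::runif(n0, 0, rectangle[2])
  for (l in seq_along(lures)) {
    sh <- beta_params_from_moments(lures[[l]]$mean_pint, lures[[l]]$var_pint)
    pint[, l] <- stats::rbeta(n0, sh[["shape1"]], sh[["shape2"]])
  }
  structure(list(hx = hx, hy = hy, pint = pint,
                 age_days = rep(3650L, n0),
                 alive = rep(TRUE, n0),
                 capture_night = rep(NA_integer_, n0),
                 rectangle = as.numeric(rectangle),
                 lures = lures),
            class = "trapshy_population")
}

#' @export
print.trapshy_population <- function(x, ...) {
  cat(sprintf(paste0("Simulated population: %d individuals (%d alive) on a ",
                     "%g x %g m rectangle\n"),
              length(x$hx), sum(x$alive), x$rectangle[1], x$rectangle[2]))
  for (l in seq_len(ncol(x$pint))) {
    cat(sprintf("  lure %s: mean p_int %.3f (alive: %.3f)\n",
                colnames(x$pint)[l], mean(x$pint[, l]),
                mean(x$pint[x$alive, l])))
  }
  invisible(x)
}

#' Traps within an individual's home range
#'
#' Returns the active traps whose Euclidean distance from a home-range
#' centre does not exceed the home-range radius `2.45 * sigma` padded by the
#' trap perception distance.
#'
#' @param centre Numeric length-2 `c(x, y)` home-range centre (m).
#' @param traps Trap layout data frame with columns `trap_id`, `x_m`, `y_m`,
#'   `active_from` (`Date`) and `lure` (see [make_square_grid()]).
#' @param sigma_m Spatial decay parameter (m, > 0).
#' @param params A [sim_params()] object (supplies the perception distance).
#' @param date Optional `Date`; when given, only traps with
#'   `active_from <= date` are considered.
#' @return The matching rows of `traps` with an extra `distance_m` column,
#'   ordered by distance.
#' @export
traps_in_range <- function(centre, traps, sigma_m, params = sim_params(),
                           date = NULL) {
  if (sigma_m <= 0) {
    stop("traps_in_range: 'sigma_m' must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(centre), length(centre) == 2L)
  tr <- traps
  if (!is.null(date)) tr <- tr[tr$active_from <= as.Date(date), , drop = FALSE]
  d <- sqrt((tr$x_m - centre[1])^2 + (tr$y_m - centre[2])^2)
  keep <- d <= home_range_radius(sigma_m) + params$perception_distance_m
  out <- tr[keep, , drop = FALSE]
  out$distance_m <- d[keep]
  out[order(out$distance_m), , drop = FALSE]
}
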