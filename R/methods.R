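#' @export
print.trapshy <- function(x, ...) {
  cat("Rejection-ABC calibration of the trap-shyness model\n")
  cat(sprintf("  %d prior draws, %d accepted (%.3g fraction), seed %d\n",
              x$n_draws, nrow(x$accepted), x$accept, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s median %.3g  [95%% CI %.3g, %.3g]  (best fit %.3g)\n",
                s$parameter[i], s$median[i], s$lo[i], s$hi[i], s$best[i]))
  }
  invisible(x)
}

#' Summarise a fitted trap-shyness model
#'
#' @param object A [trapshy()] fit.
#' @param ... Unused.
#' @return The summary data frame (parameter, median, 95% CI bounds, best
#'   fit), invisibly after printing; also reports the minimum error and the
#'   shape of the median Beta distribution.
#' @export
summary.trapshy <- function(object, ...) {
  print(object)
  med <- object$summary$median
  sh <- try(beta_params_from_moments(med[1], med[2]), silent = TRUE)
  if (!inherits(sh, "try-error")) {
    shape <- if (all(sh < 1)) "U-shaped" else "unimodal"
    cat(sprintf(paste0("  median p_int distribution: Beta(%.3g, %.3g), %s\n"),
                sh[["shape1"]], sh[["shape2"]], shape))
  }
  cat(sprintf("  minimum discrepancy: %.4g\n", min(object$posterior$error)))
  invisible(object$summary)
}

#' @export
coef.trapshy <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$parameter)
}

#' Plot ABC posterior distributions
#'
#' Marginal posterior histograms of `mu0`, `s0^2` and `N0` (best-fitting
#' value marked in red) and the Beta density of the interaction probability
#' at the posterior medians.
#'
#' @param x A [trapshy()] fit.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.trapshy <- function(x, ...) {
  acc <- x$accepted
  best <- x$best
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(mu0 = expression(mu[0]), s02 = expression(s[0]^2),
            n0 = expression(N[0]))
  for (p in c("mu0", "s02", "n0")) {
    graphics::hist(acc[[p]], main = "", xlab = labs[[p]],
                   col = "grey85", border = "white", ...)
    graphics::abline(v = best[[p]], col = "red", lwd = 2)
  }
  med <- coef(x)
  sh <- beta_params_from_moments(med[["mu0"]], med[["s02"]])
  xs <- seq(0.001, 0.999, length.out = 400)
  graphics::plot(xs, stats::dbeta(xs, sh[["shape1"]], sh[["shape2"]]),
                 type = "l", col = "red", lwd = 2,
                 xlab = expression(p[int]), ylab = "density")
  invisible(x)
}

#' Forward-simulate capture series from a fitted model
#'
#' Draws parameter triples from the accepted posterior (or reuses the
#' best-fitting triple) and runs the forward model once per draw over the
#' fitted calendar and trap layout, returning the cumulative captures at the
#' observation dates.
#'
#' @param object A [trapshy()] fit.
#' @param nsim Number of simulations.
#' @param seed Optional integer seed.
#' @param use `"posterior"` (default; resample accepted triples with
#'   replacement) or `"best"` (always the minimum-error triple).
#' @param ... Unused.
#' @return A list of `nsim` data frames (columns `date`,
#'   `cumulative_captures`).
#' @export
simulate.trapshy <- function(object, nsim = 1, seed = NULL,
                             use = c("posterior", "best"), ...) {
  use <- match.arg(use)
  if (!is.null(seed)) set.seed(seed)
  rect <- c(object$params$rect_width_m, object$params$rect_height_m)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    tr <- if (use == "best") {
      object$best
    } else {
      object$accepted[sample.int(nrow(object$accepted), 1L), ]
    }
    pop <- init_population(tr$n0, rect, lure_spec("A", tr$mu0, tr$s02))
    sim <- run_simulation(pop, object$traps, object$params, mode = "single",
                          engine = object$engine)
    out[[s]] <- capture_series(sim, object$observed$date)
  }
  out
}

#' Expected capture trajectory under the best-fitting parameters
#'
#' Median cumulative captures at the observation dates over `nreps` forward
#' simulations at the minimum-error parameter triple.
#'
#' @param object A [trapshy()] fit.
#' @param nreps Number of forward replicates (default 20).
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with columns `date`, `observed` and `predicted`.
#' @export
predict.trapshy <- function(object, nreps = 20, seed = NULL, ...) {
  sims <- simulate(object, nsim = nreps, seed = seed, use = "best")
  m <- vapply(sims, function(s) s$cumulative_captures,
              numeric(nrow(object$observed)))
  data.frame(date = object$observed$date,
             observed = object$observed$cumulative_captures,
             predicted = apply(m, 1L, stats::median))
}

#' @export
residuals.trapshy <- function(object, nreps = 20, seed = NULL, ...) {
  p <- predict(object, nreps = nreps, seed = seed)
  stats::setNames(p$observed - p$predicted, format(p$date))
}
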