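test_that("prior draws respect bounds and Beta validity", {
  pr <- abc_prior()
  set.seed(1)
  d <- sample_prior(2e4, pr)
  expect_equal(nrow(d), 2e4)
  expect_true(all(d$mu0 > 0.1 & d$mu0 < 0.9))
  expect_true(all(d$s02 > 0.01 & d$s02 < 0.2))
  expect_true(all(d$n0 >= 140 & d$n0 <= 280))
  expect_true(all(d$n0 == floor(d$n0)))
  # every draw is a valid Beta moment pair (by construction)
  expect_true(all(d$s02 < d$mu0 * (1 - d$mu0)))
})

test_that("prior truncation matches an independent rejection oracle", {
  pr <- abc_prior()
  set.seed(2)
  d <- sample_prior(1e5, pr)
  # oracle: plain rejection sampling of the same truncated joint prior
  set.seed(3)
  n_orc <- 2e5
  om <- stats::runif(n_orc, 0.1, 0.9)
  os <- stats::runif(n_orc, 0.01, 0.2)
  keep <- os < om * (1 - om)
  expect_gt(sum(keep), 1e5)
  for (col in list(c("mu0", 1), c("s02", 2))) {
    x <- d[[col[1]]]
    y <- if (col[1] == "mu0") om[keep] else os[keep]
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    expect_lt(abs(mean(x) - mean(y)), 3 * se)
  }
})

test_that("discrepancy is the mean squared error on aligned dates", {
  base <- as.Date("2021-06-01")
  a <- data.frame(date = base + c(7, 14),
                  cumulative_captures = c(1, 2))
  b <- data.frame(date = base + c(7, 14),
                  cumulative_captures = c(0, 0))
  expect_equal(discrepancy(a, a), 0)
  expect_equal(discrepancy(a, b), 2.5)
  expect_equal(discrepancy(b, a), 2.5)  # symmetric
  # permutation of rows with the same date/value pairs changes nothing
  expect_equal(discrepancy(a[2:1, ], b), 2.5)
  bad <- data.frame(date = base + c(7, 21), cumulative_captures = c(0, 0))
  expect_error(discrepancy(a, bad), "same observation dates")
})

test_that("rejection keeps exactly the stated fraction, ties by draw order", {
  set.seed(4)
  s <- data.frame(error = stats::runif(30000))
  expect_equal(sum(abc_reject(s, 0.01)$accepted), 300)
  # fraction 1 keeps everything
  expect_true(all(abc_reject(s, 1)$accepted))
  # all-equal errors: the first ceil(f * n) draws win
  tied <- data.frame(error = rep(1, 10))
  expect_equal(which(abc_reject(tied, 0.3)$accepted), 1:3)
  # accepted errors never exceed rejected errors
  r <- abc_reject(s, 0.05)
  expect_lte(max(r$error[r$accepted]), min(r$error[!r$accepted]))
  expect_error(abc_reject(s[0, , drop = FALSE]), "empty")
})

test_that("posterior summaries give medians, 95% CIs and the best triple", {
  acc <- data.frame(mu0 = c(0.2, 0.3, 0.4), s02 = c(0.05, 0.1, 0.15),
                    n0 = c(150, 200, 250), error = c(3, 1, 2))
  s <- posterior_summary(acc)
  expect_equal(s$table$median, c(0.3, 0.1, 200))
  expect_equal(s$table$best, c(0.3, 0.1, 200))  # row with error 1
  # degenerate accepted set: the CI collapses to the point
  dg <- data.frame(mu0 = rep(0.3, 5), s02 = rep(0.1, 5), n0 = rep(200, 5),
                   error = rep(1, 5))
  sd <- posterior_summary(dg)
  expect_equal(sd$table$lo, sd$table$hi)
  expect_equal(sd$table$lo, sd$table$median)
  expect_error(posterior_summary(acc[1:2, ]), "at least 3")
})

test_that("the fit orchestrates draws, simulation and rejection reproducibly", {
  st <- generate_study(seed = 31)
  f1 <- trapshy(st$captures, st$traps, n_draws = 10, accept = 0.5, seed = 32)
  expect_s3_class(f1, "trapshy")
  expect_equal(nrow(f1$accepted), 5)  # ceil(0.5 * 10)
  expect_named(f1$posterior, c("mu0", "s02", "n0", "error", "accepted"))
  # identical seed, identical posterior table
  f2 <- trapshy(st$captures, st$traps, n_draws = 10, accept = 0.5, seed = 32)
  expect_identical(f1$posterior, f2$posterior)
  # posterior CSV round-trips
  tmp <- tempfile(fileext = ".csv")
  trapshy(st$captures, st$traps, n_draws = 5, accept = 0.5, seed = 33,
          posterior_file = tmp)
  expect_equal(nrow(utils::read.csv(tmp)), 5)
  expect_error(trapshy(st$captures, st$traps, n_draws = 5, accept = 0.5),
               "seed")
})

test_that("the generating parameters score better than random prior draws", {
  st <- generate_study(seed = 41)
  p <- st$params
  rect <- c(p$rect_width_m, p$rect_height_m)
  err_of <- function(mu0, s02, n0) {
    pop <- init_population(n0, rect, lure_spec("A", mu0, s02))
    sim <- run_simulation(pop, st$traps, p)
    discrepancy(capture_series(sim, st$captures$date), st$captures)
  }
  set.seed(42)
  e_true <- err_of(st$truth$mu0, st$truth$s02, st$truth$n0)
  d <- sample_prior(20, abc_prior())
  e_rand <- vapply(seq_len(20), function(i) {
    err_of(d$mu0[i], d$s02[i], d$n0[i])
  }, numeric(1))
  expect_lt(e_true, stats::median(e_rand))
})

test_that("posterior precision degrades with observation noise", {
  width <- function(noise_sd, rep) {
    st <- generate_study(seed = 500 + rep, obs_noise_sd = noise_sd)
    f <- trapshy(st$captures, st$traps, n_draws = 600, accept = 0.05,
                 seed = 600 + rep)
    s <- f$summary
    s$hi[s$parameter == "mu0"] - s$lo[s$parameter == "mu0"]
  }
  w_clean <- mean(vapply(1:3, function(r) width(0, r), numeric(1)))
  w_noisy <- mean(vapply(1:3, function(r) width(60, r), numeric(1)))
  expect_lt(w_clean, w_noisy)
})
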