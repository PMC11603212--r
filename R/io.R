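#' Read and write capture time series
#'
#' Capture series are CSV files with ISO-8601 `date` and integer
#' `cumulative_captures` columns, plus an optional `nightly_captures`
#' column holding the per-interval count since the previous check. On read,
#' dates must be unique, counts non-negative, the cumulative column
#' non-decreasing, and (when both columns are present) the differences of
#' the cumulative column must equal the nightly column.
#'
#' @param path File path.
#' @return `read_captures()`: a data frame with a `Date` column `date`; the
#'   writer returns `path` invisibly.
#' @export
read_captures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "cumulative_captures")
  if (!all(need %in% names(df))) {
    stop("read_captures: CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) {
    stop("read_captures: unparseable dates (need ISO-8601)", call. = FALSE)
  }
  if (anyDuplicated(df$date)) {
    stop("read_captures: duplicate dates", call. = FALSE)
  }
  df <- df[order(df$date), , drop = FALSE]
  cc <- df$cumulative_captures
  if (any(cc < 0) || any(cc != floor(cc))) {
    stop("read_captures: cumulative captures must be non-negative integers",
         call. = FALSE)
  }
  if (any(diff(cc) < 0)) {
    stop("read_captures: cumulative captures must be non-decreasing",
         call. = FALSE)
  }
  if ("nightly_captures" %in% names(df)) {
    if (!isTRUE(all.equal(diff(c(0, cc)), as.numeric(df$nightly_captures)))) {
      stop("read_captures: nightly_captures inconsistent with the ",
           "differences of cumulative_captures", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_captures
#' @param series Data frame with columns `date` and `cumulative_captures`
#'   (optionally `nightly_captures`).
#' @export
write_captures <- function(series, path) {
  df <- series
  df$date <- format(as.Date(df$date))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trap layouts
#'
#' Trap layouts are CSV files with columns `trap_id`, `x_m`, `y_m`,
#' `active_from` (ISO-8601 date) and `lure`.
#'
#' @param path File path.
#' @return `read_traps()`: a validated data frame; the writer returns
#'   `path` invisibly.
#' @export
read_traps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trap_id", "x_m", "y_m", "active_from", "lure")
  if (!all(need %in% names(df))) {
    stop("read_traps: CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$active_from <- as.Date(df$active_from)
  if (anyNA(df$active_from)) {
    stop("read_traps: unparseable activation dates", call. = FALSE)
  }
  if (!is.numeric(df$x_m) || !is.numeric(df$y_m) ||
      any(df$x_m < 0) || any(df$y_m < 0)) {
    stop("read_traps: coordinates must be non-negative numbers (metres, ",
         "origin at the study-rectangle corner)", call. = FALSE)
  }
  if (anyDuplicated(df$trap_id)) {
    stop("read_traps: duplicate trap ids", call. = FALSE)
  }
  df
}

#' @rdname read_traps
#' @param traps Trap layout data frame.
#' @export
write_traps <- function(traps, path) {
  df <- traps
  df$active_from <- format(as.Date(df$active_from))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_defaults <- function() {
  p <- sim_params()
  pr <- abc_prior()
  list(
    seed = NULL,
    model = list(
      area_ha = p$area_ha, rect_width_m = p$rect_width_m,
      rect_height_m = p$rect_height_m, trap_spacing_m = p$trap_spacing_m,
      carrying_capacity = p$carrying_capacity, lifespan_yr = p$lifespan_yr,
      birth_rate_max = p$birth_rate_max,
      season_peak_doy = p$season_peak_doy,
      season_sd_days = p$season_sd_days,
      repro_onset_monthday = p$repro_onset_monthday,
      sigma_max_m = p$sigma_max_m, sigma_coeff = p$sigma_coeff,
      sigma_exp = p$sigma_exp, g0_coeff = p$g0_coeff, g0_exp = p$g0_exp,
      perception_distance_m = p$perception_distance_m, dt_days = p$dt_days,
      t0 = format(p$t0), t_end = format(p$t_end)
    ),
    prior = list(mu0_bounds = pr$mu0_bounds, s02_bounds = pr$s02_bounds,
                 n0_bounds = pr$n0_bounds),
    fit = list(n_draws = 30000L, accept = 0.01),
    scenarios = list(n_reps = 10000L, plateau_eps = 0.05,
                     rc_values = c(0.8, 0.9))
  )
}

#' Load a validated run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file,
#' fills omitted optional keys with the model defaults (the fitted-study
#' constants: `K = 9`, `l = 13`, `alpha = 0.77`, `d_traps = 100`, ...),
#' rejects unknown keys, and validates ranges. The `seed` key is mandatory.
#'
#' @param path Configuration file path.
#' @return An object of class `"trapshy_config"`: list with elements
#'   `seed`, `params` (a [sim_params()]), `prior` (an [abc_prior()]),
#'   `fit` and `scenarios`, plus `raw` (the merged key tree used by
#'   [save_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("load_config: no such file: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown) > 0L) {
    stop("load_config: unknown top-level key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$seed)) {
    stop("load_config: 'seed' is required", call. = FALSE)
  }
  if (!is.numeric(raw$seed) || raw$seed != floor(raw$seed)) {
    stop("load_config: 'seed' must be an integer", call. = FALSE)
  }
  merged <- defs
  merged$seed <- as.integer(raw$seed)
  for (sec in c("model", "prior", "fit", "scenarios")) {
    if (!is.null(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(defs[[sec]]))
      if (length(bad) > 0L) {
        stop("load_config: unknown key(s) in '", sec, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      merged[[sec]][names(raw[[sec]])] <- raw[[sec]]
    }
  }
  m <- merged$model
  params <- sim_params(
    area_ha = m$area_ha, rect_width_m = m$rect_width_m,
    rect_height_m = m$rect_height_m, trap_spacing_m = m$trap_spacing_m,
    carrying_capacity = m$carrying_capacity, lifespan_yr = m$lifespan_yr,
    birth_rate_max = m$birth_rate_max, season_peak_doy = m$season_peak_doy,
    season_sd_days = m$season_sd_days,
    repro_onset_monthday = m$repro_onset_monthday,
    sigma_max_m = m$sigma_max_m, sigma_coeff = m$sigma_coeff,
    sigma_exp = m$sigma_exp, g0_coeff = m$g0_coeff, g0_exp = m$g0_exp,
    perception_distance_m = m$perception_distance_m, dt_days = m$dt_days,
    t0 = as.Date(m$t0), t_end = as.Date(m$t_end)
  )
  prior <- abc_prior(merged$prior$mu0_bounds, merged$prior$s02_bounds,
                     merged$prior$n0_bounds)
  fit <- merged$fit
  if (fit$n_draws < 1 || fit$accept <= 0 || fit$accept > 1) {
    stop("load_config: invalid 'fit' settings", call. = FALSE)
  }
  sc <- merged$scenarios
  if (sc$n_reps < 1 || sc$plateau_eps <= 0 || sc$plateau_eps >= 1 ||
      any(sc$rc_values <= 0) || any(sc$rc_values >= 1)) {
    stop("load_config: invalid 'scenarios' settings", call. = FALSE)
  }
  structure(list(seed = merged$seed, params = params, prior = prior,
                 fit = fit, scenarios = sc, raw = merged),
            class = "trapshy_config")
}

#' @rdname load_config
#' @param config A `"trapshy_config"` object.
#' @export
save_config <- function(config, path) {
  raw <- config$raw
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an analysis bit-identically next to
#' its outputs: package version, seed, timestamp, and MD5 checksums of the
#' input files.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run.
#' @param inputs Character vector of input file paths to checksum.
#' @param extra Optional named list of additional fields to record.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, inputs = character(0),
                           extra = list()) {
  sums <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- c(list(
    package = "trapshy",
    version = as.character(utils::packageVersion("trapshy")),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_md5 = sums
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
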