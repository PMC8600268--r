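# Validated CSV readers/writers for the three input schemas and the
# end-to-end report driver.

# A schema is a list: name, cols (name -> "character"|"numeric"|"integer"|
# "date"), required (cols that must be present), check (function(df, path)
# -> character vector of problems).
schema_def <- function(name, cols, required = names(cols), check = NULL) {
  list(name = name, cols = cols, required = required, check = check)
}

rearing_schema <- schema_def(
  "rearing",
  cols = c(site = "character", elevation_m = "numeric", sex = "character",
           photoperiod = "character", tvar_c = "numeric",
           dev_days = "numeric", mass_g = "numeric", mother_id = "character"),
  required = c("site", "elevation_m", "sex", "photoperiod", "tvar_c",
               "dev_days", "mass_g"),
  check = function(df, path) {
    probs <- character(0)
    for (col in c("dev_days", "mass_g")) {
      bad <- which(df[[col]] <= 0)
      if (length(bad) > 0) {
        probs <- c(probs, sprintf("%s: row %d, column %s: must be > 0",
                                  path, bad, col))
      }
    }
    bad <- which(df$tvar_c < 0)
    if (length(bad) > 0) {
      probs <- c(probs, sprintf("%s: row %d, column tvar_c: must be >= 0",
                                path, bad))
    }
    probs
  }
)

weather_schema <- schema_def(
  "weather",
  cols = c(site = "character", date = "date", tmin_c = "numeric",
           tmax_c = "numeric"),
  check = function(df, path) {
    bad <- which(df$tmax_c < df$tmin_c)
    if (length(bad) > 0) {
      sprintf("%s: row %d, column tmax_c: tmax_c < tmin_c", path, bad)
    } else character(0)
  }
)

survey_schema <- schema_def(
  "survey",
  cols = c(site = "character", date = "date",
           stage1 = "integer", stage2 = "integer", stage3 = "integer",
           stage4 = "integer", stage5 = "integer", stage6 = "integer"),
  check = function(df, path) {
    probs <- character(0)
    for (col in paste0("stage", 1:6)) {
      bad <- which(df[[col]] < 0)
      if (length(bad) > 0) {
        probs <- c(probs, sprintf("%s: row %d, column %s: negative count",
                                  path, bad, col))
      }
    }
    probs
  }
)

#' Read and validate a CSV against a schema
#'
#' Reads a CSV (ISO dates, "." decimal point), checks the header against
#' the schema, coerces column types, and runs the schema's row-level
#' checks. Every problem is reported as `file: row N, column C: ...` (row
#' numbers count data rows, header excluded).
#'
#' @param path Path to a CSV file.
#' @param schema One of the built-in schemas (see [read_rearing_csv()] and
#'   friends, which are the usual entry points).
#' @return A validated tibble.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(schema$required, names(raw))
  if (length(missing_cols) > 0) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  probs <- character(0)
  out <- raw
  for (col in intersect(names(schema$cols), names(raw))) {
    type <- schema$cols[[col]]
    if (type == "character") next
    x <- raw[[col]]
    conv <- switch(type,
      numeric = suppressWarnings(as.numeric(x)),
      integer = suppressWarnings(as.integer(x)),
      date = as.Date(x, format = "%Y-%m-%d")
    )
    bad <- which(!is.na(x) & is.na(conv))
    if (length(bad) > 0) {
      probs <- c(probs, sprintf("%s: row %d, column %s: cannot parse '%s' as %s",
                                path, bad, col, x[bad], type))
    }
    out[[col]] <- conv
  }
  if (length(probs) == 0 && !is.null(schema$check)) {
    probs <- c(probs, schema$check(out, path))
  }
  if (length(probs) > 0) {
    stop("validation failed:\n", paste(probs, collapse = "\n"),
         call. = FALSE)
  }
  out
}

#' @rdname read_table
#' @details `read_rearing_csv()` expects columns `site, elevation_m, sex,
#'   photoperiod, tvar_c, dev_days, mass_g` (and optionally `mother_id`);
#'   `read_weather_csv()` expects `site, date, tmin_c, tmax_c`;
#'   `read_survey_csv()` expects `site, date, stage1..stage6`.
#' @export
read_rearing_csv <- function(path) read_table(path, rearing_schema)

#' @rdname read_table
#' @export
read_weather_csv <- function(path) read_table(path, weather_schema)

#' @rdname read_table
#' @export
read_survey_csv <- function(path) read_table(path, survey_schema)

#' Write a table as CSV
#'
#' ISO dates, "." decimals; the output of every pipeline stage re-reads
#' cleanly with [read_table()].
#'
#' @param x Data frame.
#' @param path Output path (directories are created).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the whole workflow on synthetic data: simulate a rearing cohort,
#' fit the development and growth Q10 models per site x photoperiod x sex,
#' normalise the Q10s, simulate weather for each site in a warm and a cool
#' season, accumulate growing degree-days, simulate weekly stage-count
#' surveys, and estimate adult timing as the DI = 5.5 crossing on both the
#' day-of-year and the cumulative-GDD axis. Writes five artefacts to
#' `out_dir`: `rearing.csv`, `q10_fits.csv`, `relative_q10.csv`, `gdd.csv`,
#' `adult_timing.csv`, plus a plain-text `summary.txt`. Deterministic given
#' the config's seed.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param years Named numeric vector: season-warmth offsets (degC) per
#'   simulated year; default one warm (+2) and one cool (-2) season.
#' @param threshold DI threshold for adult timing (default 5.5).
#' @return Invisibly, a list with the pipeline tables and output paths.
#' @export
run_report <- function(config = simulation_config(), out_dir = "results",
                       years = c("2009" = 2, "2010" = -2),
                       threshold = 5.5) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rearing <- simulate_rearing_cohort(config)
  dev_fits <- fit_development_q10(rearing)
  growth_fits <- fit_growth_q10(rearing)
  fits <- dplyr::bind_rows(dev_fits, growth_fits)
  rel <- dplyr::bind_rows(
    normalize_relative(dev_fits),
    normalize_relative(growth_fits)
  )

  weather <- dplyr::bind_rows(lapply(names(years), function(yr) {
    dplyr::bind_rows(lapply(config$sites$site, function(s) {
      simulate_weather(config, s, as.integer(yr),
                       year_offset_c = years[[yr]])
    }))
  }))
  weather$year <- as.integer(strftime(weather$date, "%Y"))
  gdd <- dplyr::bind_rows(lapply(split(weather, weather$year), function(w) {
    cumulative_gdd(w[c("site", "date", "tmin_c", "tmax_c")],
                   ldt = config$ldt)
  }))

  surveys <- dplyr::bind_rows(lapply(split(weather, weather$year),
    function(w) {
      simulate_surveys(config, w[c("site", "date", "tmin_c", "tmax_c")])
    }))
  di <- suppressWarnings(di_series(surveys, gdd = gdd))
  timing <- adult_timing_table(di, threshold = threshold)

  paths <- list(
    rearing = file.path(out_dir, "rearing.csv"),
    fits = file.path(out_dir, "q10_fits.csv"),
    relative = file.path(out_dir, "relative_q10.csv"),
    gdd = file.path(out_dir, "gdd.csv"),
    timing = file.path(out_dir, "adult_timing.csv"),
    summary = file.path(out_dir, "summary.txt")
  )
  write_table(rearing, paths$rearing)
  write_table(fits, paths$fits)
  write_table(rel, paths$relative)
  write_table(gdd, paths$gdd)
  write_table(timing, paths$timing)

  truth <- dplyr::distinct(config$design, .data$site, .data$photoperiod,
                           .data$sex, .data$q10_dev, .data$q10_growth)
  cmp <- dplyr::left_join(
    dev_fits, truth,
    by = c("site", "photoperiod", "sex")
  )
  lines <- c(
    "hopperdev pipeline report",
    sprintf("seed: %d", config$seed),
    sprintf("design cells: %d; individuals reared: %d",
            nrow(config$design), nrow(rearing)),
    sprintf("rearing noise sd: %g days, %g g",
            config$noise_sd_days, config$noise_sd_mass),
    sprintf("weather years (offset degC): %s",
            paste(sprintf("%s (%+g)", names(years), years), collapse = ", ")),
    sprintf("survey records: %d; DI points: %d", nrow(surveys), nrow(di)),
    sprintf("LDT: %g degC; DI threshold: %g", config$ldt, threshold),
    "",
    "development Q10 fits (estimate vs generative truth):",
    sprintf("  %s/%s/%s: q10_hat = %.3f (truth %.3f), converged = %s",
            cmp$site, cmp$photoperiod, cmp$sex, cmp$q10, cmp$q10_dev,
            cmp$converged),
    "",
    "adult timing (DI crossing):",
    sprintf("  %s %d: doy = %s, gdd = %s, status = %s",
            timing$site, timing$year,
            formatC(timing$doy_at_threshold, format = "f", digits = 2),
            formatC(timing$gdd_at_threshold, format = "f", digits = 1),
            timing$status)
  )
  writeLines(lines, paths$summary)

  invisible(list(
    rearing = rearing, fits = fits, relative = rel, weather = weather,
    gdd = gdd, surveys = surveys, di = di, timing = timing, paths = paths
  ))
}
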