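# Synthetic rearing cohorts, daily weather, and stage-count surveys that
# emulate a 2x2 temperature-variance x photoperiod rearing design across an
# elevation gradient, plus weekly field surveys of a GDD-driven cohort.

# Derived per-stream seeds so each generator has its own reproducible RNG
# stream under one root seed; kept below 2^31 - 1.
stream_seed <- function(seed, stream, k = 0) {
  stream_id <- c(rearing = 1, weather = 2, surveys = 3)[[stream]]
  as.integer((as.numeric(seed) %% 59999) * 31013 + stream_id * 7919 + k) %%
    2147483647L
}

# Evaluate expr with a locally-seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Gaussian noise truncated below at `lower` via inverse-CDF sampling
# (deterministic given the RNG state; no rejection loop).
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (all(sd == 0)) return(rep_len(mean, n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulation configuration for the synthetic study
#'
#' Collects every tunable of the synthetic-data module in one validated
#' list. Defaults state the emulated study design: three montane source
#' sites at 2,195 / 2,591 / 3,048 m near 40 deg N, a 2x2 rearing design of
#' high (24 +/- 4 degC, "HV") vs low (24 +/- 2 degC, "LV") diurnal
#' temperature variance crossed with long (14:10) vs short (12:12)
#' photoperiod, both sexes, ~10 individuals per design cell, seasonal
#' mountain weather with an elevation lapse, and weekly stage-count surveys
#' of a GDD-driven cohort (LDT 0 degC).
#'
#' The true Q10s behind the rearing generator encode the headline biology:
#' development Q10 is flat across sites under long days but increases with
#' elevation under short days; growth Q10 is flat everywhere.
#'
#' @param seed Root integer seed; every generator derives its own stream
#'   from it.
#' @param n_per_cell Individuals per site x photoperiod x sex x regime cell.
#' @param noise_sd_days,noise_sd_mass Additive Gaussian noise SDs on
#'   development days and adult mass (truncated > 0).
#' @param c_dev,q10_dev_long Development-model scale and long-day Q10.
#' @param q10_dev_short_range Short-day development Q10 at the lowest and
#'   highest site (linear in elevation between them).
#' @param c_growth_female,c_growth_male,q10_growth Growth-model constants.
#' @param annual_mean_c,seasonal_amplitude_c,diurnal_range_c,day_noise_sd_c,peak_doy
#'   Weather-series parameters (degC / day of year) for the lowest site.
#' @param site_offset_c Named additive temperature offsets emulating the
#'   elevation lapse.
#' @param cohort_size,survey_interval_days,detection_prob,survey_start_doy,survey_end_doy
#'   Field-survey parameters.
#' @param hatch_gdd,hatch_gdd_sd Mean and SD of the cumulative GDD at which
#'   individuals hatch (stage 1 appears).
#' @param stage_gdd Strictly increasing cumulative GDD (after hatch)
#'   required to reach stages 2..6.
#' @param ldt Lower developmental threshold used for all GDD accumulation.
#' @param daylength_beta,daylength_p0 Optional multiplicative daylength
#'   modulation of development rate, `1 + beta * (p0 - daylength)/p0`
#'   (default off, `beta = 0`) — a stand-in for short days accelerating
#'   development.
#' @return A list of class `simulation_config`, including a `design` tibble
#'   with the true `(c_dev, q10_dev, c_growth, q10_growth)` per cell and a
#'   `sites` tibble (site, elevation, latitude, temperature offset).
#' @export
simulation_config <- function(
    seed = 1L,
    n_per_cell = 10L,
    noise_sd_days = 2,
    noise_sd_mass = 0.03,
    c_dev = 100,
    q10_dev_long = 3.5,
    q10_dev_short_range = c(3.5, 6),
    c_growth_female = 0.0055,
    c_growth_male = 0.0042,
    q10_growth = 2,
    annual_mean_c = 8,
    seasonal_amplitude_c = 11,
    diurnal_range_c = 12,
    day_noise_sd_c = 2,
    peak_doy = 200,
    site_offset_c = c(A1 = 0, B1 = -2.5, C1 = -5.5),
    cohort_size = 100L,
    survey_interval_days = 7L,
    detection_prob = 0.5,
    survey_start_doy = 105L,
    survey_end_doy = 285L,
    hatch_gdd = 400,
    hatch_gdd_sd = 30,
    stage_gdd = c(150, 300, 450, 600, 750),
    ldt = 0,
    daylength_beta = 0,
    daylength_p0 = 14) {
  if (length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (any(c(noise_sd_days, noise_sd_mass, day_noise_sd_c, hatch_gdd_sd) < 0)) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (length(stage_gdd) != 5 || any(diff(stage_gdd) <= 0) ||
      any(stage_gdd <= 0)) {
    stop("`stage_gdd` must be 5 strictly increasing positive thresholds ",
         "(stages 2..6)", call. = FALSE)
  }
  if (detection_prob <= 0 || detection_prob > 1) {
    stop("`detection_prob` must lie in (0, 1]", call. = FALSE)
  }
  sites <- tibble::tibble(
    site = c("A1", "B1", "C1"),
    elevation_m = c(2195, 2591, 3048),
    latitude = c(40.01, 40.02, 40.03),
    offset_c = unname(site_offset_c[c("A1", "B1", "C1")])
  )
  if (anyNA(sites$offset_c)) {
    stop("`site_offset_c` must name sites A1, B1, C1", call. = FALSE)
  }
  design <- tidyr_expand_design(sites, q10_dev_long, q10_dev_short_range,
                                c_dev, c_growth_female, c_growth_male,
                                q10_growth)
  structure(
    list(
      seed = as.integer(seed),
      n_per_cell = as.integer(n_per_cell),
      noise_sd_days = noise_sd_days,
      noise_sd_mass = noise_sd_mass,
      sites = sites,
      design = design,
      annual_mean_c = annual_mean_c,
      seasonal_amplitude_c = seasonal_amplitude_c,
      diurnal_range_c = diurnal_range_c,
      day_noise_sd_c = day_noise_sd_c,
      peak_doy = peak_doy,
      cohort_size = as.integer(cohort_size),
      survey_interval_days = as.integer(survey_interval_days),
      detection_prob = detection_prob,
      survey_start_doy = as.integer(survey_start_doy),
      survey_end_doy = as.integer(survey_end_doy),
      hatch_gdd = hatch_gdd,
      hatch_gdd_sd = hatch_gdd_sd,
      stage_gdd = stage_gdd,
      ldt = ldt,
      daylength_beta = daylength_beta,
      daylength_p0 = daylength_p0
    ),
    class = "simulation_config"
  )
}

# Full factorial design with the true generative parameters per cell.
tidyr_expand_design <- function(sites, q10_dev_long, q10_dev_short_range,
                                c_dev, c_growth_female, c_growth_male,
                                q10_growth) {
  grid <- expand.grid(
    site = sites$site,
    photoperiod = c("long", "short"),
    sex = c("female", "male"),
    tvar_c = c(2, 4),
    stringsAsFactors = FALSE
  )
  grid <- dplyr::left_join(grid, sites[c("site", "elevation_m")], by = "site")
  elev_frac <- (grid$elevation_m - min(sites$elevation_m)) /
    diff(range(sites$elevation_m))
  grid$c_dev <- c_dev
  grid$q10_dev <- ifelse(
    grid$photoperiod == "long",
    q10_dev_long,
    q10_dev_short_range[1] + elev_frac * diff(q10_dev_short_range)
  )
  grid$c_growth <- ifelse(grid$sex == "female", c_growth_female,
                          c_growth_male)
  grid$q10_growth <- q10_growth
  tibble::as_tibble(
    grid[c("site", "elevation_m", "photoperiod", "sex", "tvar_c",
           "c_dev", "q10_dev", "c_growth", "q10_growth")]
  )
}

#' Simulate a rearing cohort
#'
#' Draws `n_per_cell` individuals per design cell with development time
#' `d = development_days(c_dev, q10_dev, tvar) + N(0, noise_sd_days)` and
#' adult mass `M = adult_mass(c_growth, d, q10_growth, tvar) +
#' N(0, noise_sd_mass)`, both truncated above 0. Deterministic given the
#' config's seed.
#'
#' @param config A [simulation_config()].
#' @return A tibble in the rearing schema: `site, elevation_m, sex,
#'   photoperiod, tvar_c, dev_days, mass_g, mother_id`.
#' @export
simulate_rearing_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(stream_seed(config$seed, "rearing"), {
    n <- config$n_per_cell
    rows <- lapply(seq_len(nrow(config$design)), function(i) {
      cell <- config$design[i, ]
      if (cell$c_dev <= 0 || cell$q10_dev <= 0 ||
          cell$c_growth <= 0 || cell$q10_growth <= 0) {
        stop("invalid generative parameters in design cell ",
             paste(cell$site, cell$photoperiod, cell$sex, cell$tvar_c,
                   sep = "/"), call. = FALSE)
      }
      mu_d <- development_days(cell$c_dev, cell$q10_dev, cell$tvar_c)
      d <- rnorm_trunc(n, mu_d, config$noise_sd_days)
      mu_m <- adult_mass(cell$c_growth, d, cell$q10_growth, cell$tvar_c)
      m <- rnorm_trunc(n, mu_m, config$noise_sd_mass)
      tibble::tibble(
        site = cell$site,
        elevation_m = cell$elevation_m,
        sex = cell$sex,
        photoperiod = cell$photoperiod,
        tvar_c = cell$tvar_c,
        dev_days = d,
        mass_g = m,
        mother_id = paste0(cell$site, "-", cell$sex, "-m",
                           (seq_len(n) - 1) %% 3 + 1)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a year of daily weather for a site
#'
#' Daily mean temperature follows a sinusoidal annual cycle peaking at
#' `peak_doy`, shifted by the site's elevation-lapse offset and an optional
#' year offset (warm vs cool seasons), with additive day-to-day Gaussian
#' noise; `tmin`/`tmax` sit a fixed diurnal range apart around the daily
#' mean, so `tmax >= tmin` always.
#'
#' @param config A [simulation_config()].
#' @param site One of the configured site codes.
#' @param year Calendar year (365 days are generated from Jan 1).
#' @param year_offset_c Additive degC offset for this season's warmth.
#' @return A tibble in the weather schema: `site, date, tmin_c, tmax_c`.
#' @export
simulate_weather <- function(config, site, year, year_offset_c = 0) {
  stopifnot(inherits(config, "simulation_config"))
  idx <- match(site, config$sites$site)
  if (is.na(idx)) stop("unknown site '", site, "'", call. = FALSE)
  seed <- stream_seed(config$seed, "weather",
                      k = idx * 100000 + (year %% 10000) * 10 +
                        round(abs(year_offset_c)))
  with_local_seed(seed, {
    doy <- 1:365
    mean_t <- config$annual_mean_c + config$sites$offset_c[idx] +
      year_offset_c +
      config$seasonal_amplitude_c *
        cos(2 * pi * (doy - config$peak_doy) / 365) +
      stats::rnorm(365, 0, config$day_noise_sd_c)
    tibble::tibble(
      site = site,
      date = as.Date(paste0(year, "-01-01")) + doy - 1,
      tmin_c = mean_t - config$diurnal_range_c / 2,
      tmax_c = mean_t + config$diurnal_range_c / 2
    )
  })
}

#' Astronomical daylength
#'
#' Hours of daylight from the standard solar-declination / hour-angle
#' approximation: declination `23.45 deg * sin(2 pi (284 + doy)/365)`,
#' half-day hour angle `acos(-tan(lat) tan(decl))`. At ~40 deg N the
#' longest day falls on doy 171-173 (summer solstice).
#'
#' @param doy Day(s) of year in `[1, 365]`.
#' @param latitude Latitude in degrees, inside (-66, 66); polar latitudes
#'   (with polar day/night) are unsupported.
#' @return Daylength in hours.
#' @examples
#' daylength(172, 40.03) # ~14.9 h
#' @export
daylength <- function(doy, latitude) {
  if (any(doy < 1 | doy > 365)) {
    stop("`doy` must lie in [1, 365]", call. = FALSE)
  }
  if (any(abs(latitude) >= 66)) {
    stop("polar latitudes (|lat| >= 66) are unsupported", call. = FALSE)
  }
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  cos_h <- pmin(1, pmax(-1, -tan(latitude * pi / 180) * tan(decl)))
  24 * acos(cos_h) / pi
}

# Per-day development-rate multiplier for the optional daylength
# modulation: 1 + beta * (p0 - daylength)/p0 (short days accelerate when
# beta > 0).
daylength_multiplier <- function(config, doy, latitude) {
  if (config$daylength_beta == 0) return(rep(1, length(doy)))
  1 + config$daylength_beta *
    (config$daylength_p0 - daylength(doy, latitude)) / config$daylength_p0
}

#' Simulate weekly stage-count field surveys
#'
#' Advances a cohort of individuals through six developmental stages
#' (instars 1-5, adult = 6) driven by cumulative growing degree-days from
#' the supplied weather: individual i hatches when cumulative GDD passes
#' its hatching requirement (Gaussian across individuals) and reaches stage
#' s when a further `stage_gdd[s-1]` has accrued. When the daylength
#' modulation is enabled each day's degree-days are scaled by the
#' daylength-dependent rate multiplier before accumulation. Surveys at the
#' configured interval detect each hatched individual independently with
#' `detection_prob` and tabulate the detected stages.
#'
#' @param config A [simulation_config()].
#' @param weather Weather tibble (one or more sites, one year per site)
#'   covering the survey window, e.g. from [simulate_weather()].
#' @return A tibble in the survey schema: `site, date, stage1 .. stage6`.
#' @export
simulate_surveys <- function(config, weather) {
  stopifnot(inherits(config, "simulation_config"))
  gdd_all <- cumulative_gdd(weather, ldt = config$ldt)
  parts <- lapply(split(gdd_all, gdd_all$site), function(g) {
    idx <- match(g$site[1], config$sites$site)
    if (is.na(idx)) stop("unknown site '", g$site[1], "'", call. = FALSE)
    if (max(g$doy) < config$survey_end_doy ||
        min(g$doy) > config$survey_start_doy) {
      stop("weather for site '", g$site[1],
           "' does not cover the survey window", call. = FALSE)
    }
    mult <- daylength_multiplier(config, g$doy, config$sites$latitude[idx])
    eff_gdd <- cumsum(g$dd * mult)
    year <- as.integer(strftime(g$date[1], "%Y"))
    seed <- stream_seed(config$seed, "surveys",
                        k = idx * 100000 + (year %% 10000))
    with_local_seed(seed, {
      hatch <- rnorm_trunc(config$cohort_size, config$hatch_gdd,
                           config$hatch_gdd_sd, lower = 1e-6)
      survey_doys <- seq(config$survey_start_doy, config$survey_end_doy,
                         by = config$survey_interval_days)
      recs <- lapply(survey_doys, function(d) {
        row <- match(d, g$doy)
        e <- eff_gdd[row]
        # stage of each individual: 0 = unhatched, else 1 + thresholds passed
        stage <- ifelse(
          e < hatch, 0L,
          1L + vapply(pmax(e - hatch, 0),
                      function(x) sum(config$stage_gdd <= x), integer(1))
        )
        stage <- pmin(stage, 6L)
        present <- which(stage >= 1L)
        detected <- present[stats::runif(length(present)) <=
                              config$detection_prob]
        counts <- tabulate(stage[detected], nbins = 6L)
        tibble::tibble(
          site = g$site[1], date = g$date[row],
          stage1 = counts[1], stage2 = counts[2], stage3 = counts[3],
          stage4 = counts[4], stage5 = counts[5], stage6 = counts[6]
        )
      })
      dplyr::bind_rows(recs)
    })
  })
  dplyr::bind_rows(parts)
}
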