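# Growing degree-days from daily Tmin/Tmax by the single-sine approximation.

#' Daily degree-days by the single-sine approximation
#'
#' Models the daily temperature course as one symmetric sine wave between
#' `tmin` and `tmax` with a fixed 12 h spacing between the minimum and the
#' maximum, and integrates the part of the curve above the lower
#' developmental threshold (LDT). With mean `Tm = (tmin + tmax)/2` and
#' half-range `a = (tmax - tmin)/2`:
#'
#' * `ldt <= tmin`: the whole sine is above threshold, dd = `Tm - ldt`;
#' * `ldt >= tmax`: nothing accrues, dd = 0;
#' * otherwise the sine is intercepted and
#'   dd = \eqn{(1/\pi)[(T_m - ldt)(\pi/2 - \theta) + a\cos\theta]} with
#'   \eqn{\theta = \arcsin((ldt - T_m)/a)}.
#'
#' The three cases join continuously at `ldt = tmin` and `ldt = tmax`.
#'
#' @param tmin,tmax Daily minimum and maximum air temperature (degC,
#'   vectorised; requires `tmax >= tmin`).
#' @param ldt Lower developmental threshold (degC). Default 0, the
#'   rearing-derived threshold used for this species (12 degC is the older
#'   multi-species field value).
#' @return Degree-days (degC * day, >= 0).
#' @examples
#' daily_degree_days(10, 20, 0)  # 15
#' daily_degree_days(-5, 15, 0)  # 6.09: sine intercepted by the threshold
#' @export
daily_degree_days <- function(tmin, tmax, ldt = 0) {
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n)
  tmax <- rep_len(tmax, n)
  bad <- which(tmax < tmin)
  if (length(bad) > 0) {
    stop("tmax < tmin at position(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tmean <- (tmin + tmax) / 2
  alpha <- (tmax - tmin) / 2
  dd <- numeric(n)
  above <- ldt <= tmin
  below <- ldt >= tmax
  mid <- !above & !below # implies alpha > 0
  dd[above] <- tmean[above] - ldt
  dd[below] <- 0
  if (any(mid)) {
    theta <- asin((ldt - tmean[mid]) / alpha[mid])
    dd[mid] <- (1 / pi) *
      ((tmean[mid] - ldt) * (pi / 2 - theta) + alpha[mid] * cos(theta))
  }
  dd
}

#' Cumulative growing degree-days per site
#'
#' Applies [daily_degree_days()] to an ordered daily weather table and
#' accumulates the running sum (physiological time) from a starting day of
#' year, separately per site.
#'
#' @param weather Data frame with columns `site`, `date` (Date), `tmin_c`,
#'   `tmax_c` (see [read_weather_csv()]).
#' @param ldt Lower developmental threshold (degC), default 0.
#' @param start_doy 1-based day of year at which accumulation starts
#'   (default 1 = Jan 1); earlier days get `dd = 0` contribution.
#' @param allow_gaps If `FALSE` (default) missing calendar days within a
#'   site's series are an error; if `TRUE` gaps are skipped with a warning
#'   and the result carries `attr(*, "contiguous") = FALSE` (cumulative
#'   values are then lower bounds).
#' @return A tibble `site, date, doy, dd, gdd` with `gdd` non-decreasing
#'   within site.
#' @export
cumulative_gdd <- function(weather, ldt = 0, start_doy = 1,
                           allow_gaps = FALSE) {
  req <- c("site", "date", "tmin_c", "tmax_c")
  if (!all(req %in% names(weather))) {
    stop("`weather` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  contiguous <- TRUE
  parts <- lapply(split(weather, weather$site), function(w) {
    if (is.unsorted(w$date, strictly = FALSE)) {
      stop("weather dates are not sorted for site '", w$site[1], "'",
           call. = FALSE)
    }
    if (anyDuplicated(w$date)) {
      stop("duplicate weather date for site '", w$site[1], "'",
           call. = FALSE)
    }
    gaps <- diff(as.integer(w$date)) != 1L
    if (any(gaps)) {
      if (!allow_gaps) {
        stop("missing weather day(s) for site '", w$site[1],
             "' after ", w$date[which(gaps)[1]],
             " (use allow_gaps = TRUE to skip)", call. = FALSE)
      }
      warning("site '", w$site[1], "': ", sum(gaps),
              " gap(s) in the weather series; cumulative GDD is a lower bound",
              call. = FALSE)
      contiguous <<- FALSE
    }
    doy <- as.integer(strftime(w$date, "%j"))
    dd <- daily_degree_days(w$tmin_c, w$tmax_c, ldt)
    dd[doy < start_doy] <- 0
    tibble::tibble(site = w$site, date = w$date, doy = doy, dd = dd,
                   gdd = cumsum(dd))
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "contiguous") <- contiguous
  out
}

#' Seasonal degree-day total within a day-of-year window
#'
#' Sums daily degree-days over a doy window, per site — the season-warmth
#' measure used to rank years warm to cool.
#'
#' @inheritParams cumulative_gdd
#' @param window Length-2 numeric `c(first_doy, last_doy)`, inclusive.
#' @return A tibble `site, season_gdd`.
#' @export
season_gdd <- function(weather, ldt = 0, window = c(1, 365)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  series <- cumulative_gdd(weather, ldt = ldt, start_doy = 1,
                           allow_gaps = TRUE)
  inside <- series$doy >= window[1] & series$doy <= window[2]
  if (!any(inside)) {
    stop("no weather days fall inside the doy window [", window[1], ", ",
         window[2], "]", call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(series[inside, ], .data$site),
                   season_gdd = sum(.data$dd), .groups = "drop")
}
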