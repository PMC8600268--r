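# Development index, spline smoothing, and adult-timing estimation.

#' Development index of a stage-count sample
#'
#' The count-weighted mean developmental stage of a sampled population,
#' with stages coded 1-5 for the juvenile instars and 6 for adults:
#' DI = sum(stage * count) / sum(count). Ranges from 1 (all first instars)
#' to 6 (all adults) and is invariant to rescaling all counts.
#'
#' @param counts Numeric vector of 6 non-negative counts (stages 1..6), or
#'   a matrix/data frame with 6 such columns (one row per survey).
#' @return DI value(s) in \[1, 6\].
#' @examples
#' development_index(c(0, 0, 2, 0, 1, 1)) # 4.25
#' @export
development_index <- function(counts) {
  m <- if (is.data.frame(counts)) as.matrix(counts) else counts
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (ncol(m) != 6) stop("expected 6 stage-count columns", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("all-zero stage counts in row(s) ",
         paste(which(tot == 0), collapse = ", "), call. = FALSE)
  }
  as.numeric(m %*% (1:6)) / tot
}

#' Build development-index points from survey records
#'
#' Converts raw stage-count survey records into one DI point per survey,
#' dropping (with a warning) records where no individuals were detected,
#' and attaching the cumulative GDD at each survey date when a degree-day
#' series is supplied.
#'
#' @param surveys Data frame with columns `site`, `date`, and
#'   `stage1`..`stage6` (see [read_survey_csv()]).
#' @param gdd Optional degree-day series from [cumulative_gdd()] used to
#'   look up `gdd` at each survey's site and date.
#' @return A tibble `site, year, date, doy, di, n_individuals` (plus `gdd`
#'   if supplied).
#' @export
di_series <- function(surveys, gdd = NULL) {
  req <- c("site", "date", paste0("stage", 1:6))
  if (!all(req %in% names(surveys))) {
    stop("`surveys` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  counts <- as.matrix(surveys[paste0("stage", 1:6)])
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " survey record(s) with zero detections dropped",
            call. = FALSE)
    surveys <- surveys[tot > 0, , drop = FALSE]
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  out <- tibble::tibble(
    site = surveys$site,
    year = as.integer(strftime(surveys$date, "%Y")),
    date = surveys$date,
    doy = as.integer(strftime(surveys$date, "%j")),
    di = development_index(counts),
    n_individuals = tot
  )
  if (!is.null(gdd)) {
    out <- dplyr::left_join(
      out, dplyr::select(gdd, "site", "date", "gdd"),
      by = c("site", "date")
    )
    if (anyNA(out$gdd)) {
      stop("no degree-day value for some survey dates; ",
           "supply a weather series covering the surveys", call. = FALSE)
    }
  }
  out
}

#' Smooth a development-index series
#'
#' Fits a cubic smoothing spline to DI against day of year or cumulative
#' GDD for one site-year, the smoothing parameter chosen by generalised
#' cross-validation unless `spar` is given. Surveys sharing an axis value
#' are first averaged (weighted by individuals counted). Fitted values are
#' clamped to the feasible DI range \[1, 6\] on prediction.
#'
#' @param points A tibble from [di_series()] restricted to one site-year
#'   (columns `di`, `n_individuals`, and the axis column).
#' @param axis `"doy"` or `"gdd"`: the physiological-time axis.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; default `NULL` uses GCV.
#' @return An object of class `di_curve` (fields `spline`, `axis`,
#'   `range`, `n_points`), or a degenerate `di_curve` with
#'   `status = "insufficient_data"` when fewer than 4 distinct axis values
#'   are available.
#' @export
smooth_di_series <- function(points, axis = c("doy", "gdd"), spar = NULL) {
  axis <- match.arg(axis)
  if (!axis %in% names(points)) {
    stop("axis column '", axis, "' not present in `points`", call. = FALSE)
  }
  x <- points[[axis]]
  y <- points$di
  w <- if ("n_individuals" %in% names(points)) points$n_individuals
       else rep(1, length(x))
  # average ties (weighted by count) so the axis is strictly increasing
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(x = x, y = y, w = w), .data$x),
    y = stats::weighted.mean(.data$y, .data$w), w = sum(.data$w),
    .groups = "drop"
  )
  agg <- agg[order(agg$x), ]
  if (nrow(agg) < 4) {
    return(structure(
      list(spline = NULL, axis = axis, range = range(agg$x),
           n_points = nrow(agg), status = "insufficient_data"),
      class = "di_curve"
    ))
  }
  args <- list(x = agg$x, y = agg$y, w = agg$w, cv = FALSE,
               keep.data = FALSE)
  if (!is.null(spar)) args$spar <- spar
  sp <- do.call(stats::smooth.spline, args)
  structure(
    list(spline = sp, axis = axis, range = range(agg$x),
         n_points = nrow(agg), status = "fitted"),
    class = "di_curve"
  )
}

#' Evaluate a fitted DI curve
#'
#' @param object A `di_curve` from [smooth_di_series()].
#' @param x Axis values inside the observed range (no extrapolation).
#' @param ... Unused.
#' @return Fitted DI values clamped to \[1, 6\].
#' @export
predict.di_curve <- function(object, x, ...) {
  if (object$status != "fitted") {
    stop("cannot predict from an unfitted DI curve (status: ",
         object$status, ")", call. = FALSE)
  }
  pmin(pmax(stats::predict(object$spline, x)$y, 1), 6)
}

#' @export
print.di_curve <- function(x, ...) {
  cat(sprintf("DI curve on %s [%g, %g], %d points, status: %s\n",
              x$axis, x$range[1], x$range[2], x$n_points, x$status))
  invisible(x)
}

#' Estimate adult timing as the DI threshold crossing
#'
#' Locates the first upward crossing of the smoothed development index
#' through a threshold (default DI = 5.5, just below the all-adult
#' asymptote at 6 and near the curve's inflection) within the observed axis
#' range, by bracketing on a fine grid and root refinement to 1e-3 axis
#' units. No extrapolation: if the fitted curve never reaches the threshold
#' the status is `"not_reached"`; if the series already starts above it,
#' the first observed axis value is returned with `boundary = TRUE`.
#'
#' @param curve A `di_curve` from [smooth_di_series()].
#' @param threshold DI threshold in (1, 6); default 5.5.
#' @return A one-row tibble `axis, value, threshold, status, boundary`
#'   where `value` is the axis position (doy or cumulative GDD) of the
#'   crossing (`NA` unless `status == "estimated"`).
#' @export
estimate_adult_timing <- function(curve, threshold = 5.5) {
  stopifnot(inherits(curve, "di_curve"))
  if (!is.numeric(threshold) || threshold <= 1 || threshold >= 6) {
    stop("`threshold` must lie in (1, 6)", call. = FALSE)
  }
  out <- function(value, status, boundary = FALSE) {
    tibble::tibble(axis = curve$axis, value = value, threshold = threshold,
                   status = status, boundary = boundary)
  }
  if (curve$status != "fitted") return(out(NA_real_, curve$status))
  grid <- seq(curve$range[1], curve$range[2], length.out = 512)
  f <- predict(curve, grid) - threshold
  if (f[1] >= 0) return(out(curve$range[1], "estimated", boundary = TRUE))
  up <- which(f[-length(f)] < 0 & f[-1] >= 0)
  if (length(up) == 0) return(out(NA_real_, "not_reached"))
  i <- up[1]
  root <- stats::uniroot(
    function(z) predict(curve, z) - threshold,
    lower = grid[i], upper = grid[i + 1], tol = 1e-3
  )$root
  out(root, "estimated")
}

#' Adult-timing table for all site-years
#'
#' Convenience wrapper running [smooth_di_series()] and
#' [estimate_adult_timing()] per site and year on both the day-of-year and
#' (if available) the cumulative-GDD axis.
#'
#' @param points A [di_series()] tibble (with a `gdd` column for the GDD
#'   axis).
#' @param threshold DI threshold, default 5.5.
#' @param spar Optional smoothing parameter forwarded to the spline.
#' @return A tibble `site, year, threshold, doy_at_threshold,
#'   gdd_at_threshold, status` (`status` from the doy-axis fit; an axis
#'   whose fit failed yields `NA` for that column).
#' @export
adult_timing_table <- function(points, threshold = 5.5, spar = NULL) {
  axes <- c("doy", if ("gdd" %in% names(points)) "gdd")
  groups <- dplyr::group_split(dplyr::group_by(points, .data$site, .data$year))
  rows <- lapply(groups, function(df) {
    est <- lapply(axes, function(ax) {
      estimate_adult_timing(smooth_di_series(df, axis = ax, spar = spar),
                            threshold = threshold)
    })
    names(est) <- axes
    tibble::tibble(
      site = df$site[1], year = df$year[1], threshold = threshold,
      doy_at_threshold = est$doy$value,
      gdd_at_threshold = if ("gdd" %in% axes) est$gdd$value else NA_real_,
      status = est$doy$status
    )
  })
  dplyr::bind_rows(rows)
}
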