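# Development index, DI smoothing, and adult-timing estimation.

test_that("development_index is the count-weighted mean stage", {
  expect_equal(development_index(c(0, 0, 0, 0, 0, 12)), 6)
  expect_equal(development_index(c(7, 0, 0, 0, 0, 0)), 1)
  expect_equal(development_index(c(0, 0, 2, 0, 1, 1)), 4.25)
  # scale invariance
  x <- c(3, 1, 4, 1, 5, 9)
  expect_equal(development_index(10 * x), development_index(x))
  expect_error(development_index(c(0, 0, 0, 0, 0, 0)), "all-zero")
  expect_error(development_index(c(-1, 0, 0, 0, 0, 2)), "non-negative")
})

test_that("di_series builds points, drops empty records, joins gdd", {
  surveys <- tibble::tibble(
    site = "S", date = as.Date("2003-05-01") + c(0, 7, 14),
    stage1 = c(5, 0, 0), stage2 = c(0, 5, 0), stage3 = c(0, 0, 0),
    stage4 = c(0, 0, 0), stage5 = c(0, 0, 0), stage6 = c(0, 0, 0)
  )
  expect_warning(pts <- di_series(surveys), "zero detections")
  expect_equal(nrow(pts), 2)
  expect_equal(pts$di, c(1, 2))
  expect_equal(pts$year, c(2003L, 2003L))

  w <- constant_weather(250, 10, 20, site = "S",
                        start = as.Date("2003-01-01"))
  gdd <- cumulative_gdd(w)
  expect_warning(pts2 <- di_series(surveys, gdd = gdd), "zero detections")
  expect_equal(pts2$gdd, gdd$gdd[match(pts2$date, gdd$date)])
})

test_that("smoothing spline reproduces exact structure", {
  # collinear points -> the zero-roughness solution is the line itself
  pts <- tibble::tibble(site = "S", year = 2000, doy = seq(100, 190, 10),
                        di = 1 + 0.05 * (seq(100, 190, 10) - 100),
                        n_individuals = 20)
  curve <- smooth_di_series(pts, axis = "doy")
  expect_equal(predict(curve, pts$doy), pts$di, tolerance = 1e-6)

  # noiseless logistic over 20 surveys: fitted deviation < 0.05
  doys <- seq(100, 215, length.out = 20)
  lpts <- logistic_di_points(doys, t0 = 150, s = 6)
  lcurve <- smooth_di_series(lpts, axis = "doy")
  expect_lt(max(abs(predict(lcurve, doys) - lpts$di)), 0.05)

  # duplicate axis values are averaged before fitting
  dup <- rbind(pts, pts[3, ])
  dup$di[nrow(dup)] <- dup$di[nrow(dup)] + 0.4
  dcurve <- smooth_di_series(dup, axis = "doy")
  expect_s3_class(dcurve, "di_curve")
  expect_equal(dcurve$status, "fitted")
  expect_equal(dcurve$n_points, 10)

  # too few points propagates insufficient_data
  short <- pts[1:3, ]
  scurve <- smooth_di_series(short, axis = "doy")
  expect_equal(scurve$status, "insufficient_data")
  est <- estimate_adult_timing(scurve)
  expect_equal(est$status, "insufficient_data")
  expect_true(is.na(est$value))
})

test_that("predictions are clamped to the DI range", {
  withr::with_seed(31, {
    doys <- seq(100, 220, length.out = 25)
    pts <- logistic_di_points(doys, t0 = 140, s = 4)
    pts$di <- pmin(pmax(pts$di + rnorm(25, 0, 0.2), 1), 6)
    curve <- smooth_di_series(pts, axis = "doy")
    pred <- predict(curve, seq(100, 220, by = 0.5))
    expect_true(all(pred >= 1 & pred <= 6))
  })
})

test_that("adult timing finds the DI = 5.5 crossing of a known logistic", {
  s <- 5
  t0 <- 160 - s * log(9) # analytic crossing at exactly doy 160
  doys <- seq(100, 215, length.out = 24)
  pts <- logistic_di_points(doys, t0 = t0, s = s)
  est <- estimate_adult_timing(smooth_di_series(pts, axis = "doy"))
  expect_equal(est$status, "estimated")
  expect_false(est$boundary)
  expect_equal(est$value, 160, tolerance = 0.5 / 160)
})

test_that("left-shifting the DI curve shifts the estimate accordingly", {
  s <- 5
  t0 <- 160 - s * log(9)
  doys <- seq(100, 215, length.out = 24)
  base <- estimate_adult_timing(
    smooth_di_series(logistic_di_points(doys, t0 = t0, s = s), axis = "doy")
  )$value
  for (k in c(5, 12)) {
    shifted <- estimate_adult_timing(
      smooth_di_series(logistic_di_points(doys, t0 = t0 - k, s = s),
                       axis = "doy")
    )$value
    expect_equal(shifted, base - k, tolerance = 0.5 / base)
  }
})

test_that("adult timing statuses: not_reached and boundary start", {
  doys <- seq(100, 215, length.out = 20)
  # curve topping out below threshold
  low <- tibble::tibble(site = "S", year = 2000, doy = doys,
                        di = 1 + 3.8 / (1 + exp(-(doys - 150) / 6)),
                        n_individuals = 30)
  est <- estimate_adult_timing(smooth_di_series(low, axis = "doy"))
  expect_equal(est$status, "not_reached")
  expect_true(is.na(est$value))
  # series already above threshold at the first survey
  high <- tibble::tibble(site = "S", year = 2000, doy = doys,
                         di = pmin(5.8 + 0.002 * (doys - 100), 6),
                         n_individuals = 30)
  est2 <- estimate_adult_timing(smooth_di_series(high, axis = "doy"))
  expect_equal(est2$status, "estimated")
  expect_true(est2$boundary)
  expect_equal(est2$value, doys[1])
  expect_error(estimate_adult_timing(smooth_di_series(high), threshold = 7),
               "threshold")
})

test_that("adult_timing_table estimates per site-year on both axes", {
  doys <- seq(100, 215, by = 5)
  pts <- rbind(
    logistic_di_points(doys, t0 = 150, s = 5, site = "A1", year = 2009),
    logistic_di_points(doys, t0 = 165, s = 5, site = "A1", year = 2010)
  )
  pts$gdd <- 12 * (pts$doy - 60) # exactly GDD-driven axis
  tab <- adult_timing_table(pts)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$status, c("estimated", "estimated"))
  expect_lt(tab$doy_at_threshold[1], tab$doy_at_threshold[2])
  expect_equal(tab$gdd_at_threshold, 12 * (tab$doy_at_threshold - 60),
               tolerance = 1e-2)
})
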