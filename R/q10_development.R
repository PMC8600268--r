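# Fluctuating-temperature Q10 models for development time and adult mass,
# grouped nonlinear least-squares fits, and relative normalisation.

# bracket term shared by both models: Q10^(Tvar/10) + Q10^(-Tvar/10).
# Equals 2 at tvar = 0 or q10 = 1 and grows with |tvar| for q10 != 1.
q10_bracket <- function(q10, tvar) q10^(tvar / 10) + q10^(-tvar / 10)

#' Development time under a diurnal square-wave regime
#'
#' Days to adulthood as a function of the temperature half-amplitude
#' `tvar` of a square-wave regime spending 12 h per day at each of
#' mean +/- tvar. A fixed number of developmental units is assumed, accrued
#' at Q10-scaled rates in the warm and cool phases, giving
#' \deqn{d = c / (Q_{10}^{T_{var}/10} + Q_{10}^{-T_{var}/10}).}
#' With `q10 > 1` development accelerates as `tvar` grows: the warm-phase
#' speed-up outweighs the cool-phase slow-down.
#'
#' @param c_const Scale constant (> 0), in developmental units; equals twice
#'   the development time at `tvar = 0`.
#' @param q10 Thermal sensitivity of development (> 0).
#' @param tvar Temperature half-amplitude(s), degC >= 0 (vectorised).
#' @return Development time in days.
#' @examples
#' development_days(100, 4, 4) # 43.19
#' @export
development_days <- function(c_const, q10, tvar) {
  if (!is.numeric(c_const) || any(c_const <= 0)) {
    stop("`c_const` must be positive", call. = FALSE)
  }
  if (!is.numeric(q10) || any(q10 <= 0)) {
    stop("`q10` must be positive", call. = FALSE)
  }
  if (any(tvar < 0)) stop("`tvar` must be >= 0", call. = FALSE)
  c_const / q10_bracket(q10, tvar)
}

#' Adult mass under a diurnal square-wave regime
#'
#' Adult mass given an observed development time `d`, with growth accruing
#' at Q10-scaled rates over the warm and cool phases:
#' \deqn{M = c \, d \, (Q_{10}^{T_{var}/10} + Q_{10}^{-T_{var}/10}).}
#' If `d` itself follows [development_days()] with the *same* Q10, the
#' bracket terms cancel and mass is independent of `tvar` — the model's
#' built-in decoupling of development time and final size.
#'
#' @param c_const Growth scale constant (> 0), g per day per rate unit.
#' @param d Development time in days (> 0).
#' @param q10 Thermal sensitivity of growth (> 0).
#' @param tvar Temperature half-amplitude(s), degC >= 0.
#' @return Adult mass in grams.
#' @examples
#' adult_mass(0.005, 43.19, 4, 4) # ~0.5 g
#' @export
adult_mass <- function(c_const, d, q10, tvar) {
  if (!is.numeric(c_const) || any(c_const <= 0)) {
    stop("`c_const` must be positive", call. = FALSE)
  }
  if (any(d <= 0)) stop("`d` must be positive", call. = FALSE)
  if (!is.numeric(q10) || any(q10 <= 0)) {
    stop("`q10` must be positive", call. = FALSE)
  }
  if (any(tvar < 0)) stop("`tvar` must be >= 0", call. = FALSE)
  c_const * d * q10_bracket(q10, tvar)
}

# Shared grouped-NLS driver. `formula` references columns of `data` plus
# parameters c_const and q10; `start_fun(df)` returns the start list.
fit_q10_grouped <- function(data, group_by, formula, start_fun, model_name) {
  stopifnot(is.data.frame(data))
  missing_keys <- setdiff(group_by, names(data))
  if (length(missing_keys) > 0) {
    stop("grouping columns not in data: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  groups <- dplyr::group_split(dplyr::group_by(
    data, dplyr::across(dplyr::all_of(group_by))
  ))
  fits <- lapply(groups, function(df) {
    key <- df[1, group_by, drop = FALSE]
    label <- paste(unlist(lapply(key, as.character)), collapse = "/")
    if (length(unique(df$tvar_c)) < 2) {
      stop("group '", label, "' has a single distinct tvar_c; ",
           "(c, q10) are unidentifiable with one design point", call. = FALSE)
    }
    start <- start_fun(df)
    fit <- tryCatch(
      stats::nls(
        formula, data = df, start = start, algorithm = "port",
        lower = c(c_const = 1e-12, q10 = 0.1),
        upper = c(c_const = Inf, q10 = 20),
        control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                     warnOnly = FALSE)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      out <- key
      out$model <- model_name
      out$c_const <- NA_real_
      out$q10 <- NA_real_
      out$residual_sd <- NA_real_
      out$n_obs <- nrow(df)
      out$converged <- FALSE
      return(tibble::as_tibble(out))
    }
    cf <- stats::coef(fit)
    out <- key
    out$model <- model_name
    out$c_const <- unname(cf["c_const"])
    out$q10 <- unname(cf["q10"])
    out$residual_sd <- stats::sigma(fit)
    out$n_obs <- nrow(df)
    out$converged <- fit$convInfo$isConv
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(fits)
}

#' Fit the development-time Q10 model per group
#'
#' Estimates `(c, Q10)` by nonlinear least squares of observed development
#' days against [development_days()], independently for each combination of
#' the grouping keys (the study design groups by site, photoperiod, and
#' sex). Starts are `q10 = 2`, `c = 2 * mean(d)`; bounds `q10` in
#' `[0.1, 20]`, `c > 0`.
#'
#' @param observations Data frame with at least columns `tvar_c` and
#'   `dev_days` plus the grouping columns (see [read_rearing_csv()] for the
#'   full rearing schema).
#' @param group_by Character vector of grouping columns; default
#'   `c("site", "photoperiod", "sex")`.
#' @return A tibble with one row per group: grouping keys, `model`,
#'   `c_const`, `q10`, `residual_sd`, `n_obs`, `converged`. A group whose
#'   optimiser fails is returned with `converged = FALSE` and `NA`
#'   estimates; a group with a single distinct `tvar_c` is an error (the
#'   two-parameter model is unidentifiable from one design point).
#' @seealso [fit_growth_q10()], [normalize_relative()]
#' @export
fit_development_q10 <- function(observations,
                                group_by = c("site", "photoperiod", "sex")) {
  req <- c("tvar_c", "dev_days")
  if (!all(req %in% names(observations))) {
    stop("`observations` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(observations$dev_days <= 0)) {
    stop("`dev_days` must be positive", call. = FALSE)
  }
  fit_q10_grouped(
    observations, group_by,
    dev_days ~ c_const / (q10^(tvar_c / 10) + q10^(-tvar_c / 10)),
    function(df) list(c_const = 2 * mean(df$dev_days), q10 = 2),
    "development"
  )
}

#' Fit the growth (adult mass) Q10 model per group
#'
#' Estimates `(c, Q10)` by nonlinear least squares of observed adult mass
#' against [adult_mass()], with the observed development time entering as a
#' known covariate. Grouping and bounds as in [fit_development_q10()];
#' starts are `q10 = 2`, `c = mean(M / (2 d))`.
#'
#' @param observations Data frame with at least columns `tvar_c`,
#'   `dev_days`, and `mass_g` plus the grouping columns.
#' @inheritParams fit_development_q10
#' @return A tibble as in [fit_development_q10()], with `model = "growth"`.
#' @export
fit_growth_q10 <- function(observations,
                           group_by = c("site", "photoperiod", "sex")) {
  req <- c("tvar_c", "dev_days", "mass_g")
  if (!all(req %in% names(observations))) {
    stop("`observations` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(observations$mass_g <= 0) || any(observations$dev_days <= 0)) {
    stop("`mass_g` and `dev_days` must be positive", call. = FALSE)
  }
  fit_q10_grouped(
    observations, group_by,
    mass_g ~ c_const * dev_days * (q10^(tvar_c / 10) + q10^(-tvar_c / 10)),
    function(df) list(c_const = mean(df$mass_g / (2 * df$dev_days)), q10 = 2),
    "growth"
  )
}

#' Normalise fitted Q10s relative to the largest
#'
#' Rescales fitted Q10 estimates so the highest equals exactly 1,
#' preserving order and ratios — the convention used to compare thermal
#' sensitivities across groups on a shared relative axis. By default all
#' fits passed in one call are normalised together; `within` normalises
#' separately inside each level of the named columns (e.g. per sex).
#'
#' @param fits A tibble of fits as returned by [fit_development_q10()] /
#'   [fit_growth_q10()] (needs a positive `q10` column), or a bare numeric
#'   vector of Q10s.
#' @param within Optional character vector of columns defining separate
#'   normalisation sets.
#' @return The input with a `relative_q10` column in (0, 1] (or, for a
#'   numeric input, the normalised numeric vector).
#' @examples
#' normalize_relative(c(2, 4)) # 0.5 1
#' @export
normalize_relative <- function(fits, within = NULL) {
  if (is.numeric(fits)) {
    if (length(fits) == 0) stop("no Q10 values to normalise", call. = FALSE)
    if (any(!is.finite(fits) | fits <= 0)) {
      stop("Q10 values must be positive and finite", call. = FALSE)
    }
    return(fits / max(fits))
  }
  stopifnot(is.data.frame(fits))
  if (nrow(fits) == 0) stop("no fits to normalise", call. = FALSE)
  ok <- is.finite(fits$q10) & fits$q10 > 0
  if (!any(ok)) stop("no positive finite Q10 estimates", call. = FALSE)
  if (is.null(within)) {
    fits$relative_q10 <- fits$q10 / max(fits$q10[ok])
  } else {
    fits <- dplyr::mutate(
      dplyr::group_by(fits, dplyr::across(dplyr::all_of(within))),
      relative_q10 = .data$q10 / max(.data$q10[is.finite(.data$q10) &
                                                 .data$q10 > 0])
    )
    fits <- dplyr::ungroup(fits)
  }
  fits
}
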