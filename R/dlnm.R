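#' Fit the time-varying distributed lag nonlinear model
#'
#' Quasi-Poisson (log-link) regression of daily death counts on the
#' temperature-lag cross-basis, an interaction of the cross-basis with a
#' scaled date (so the exposure-response surface can drift over the study
#' period, capturing long-term adaptation), a day-of-week factor, a natural
#' cubic spline of date for the long-term trend (one degree of freedom per
#' decade, rounded up) and a natural cubic spline of day-of-season with four
#' degrees of freedom for within-season seasonality.  The overdispersion
#' scale is estimated from Pearson residuals and inflates the coefficient
#' covariance, as is standard quasi-likelihood practice.
#'
#' The interaction date is affinely mapped to `[-0.5, 0.5]` over the study
#' period and centered at its midpoint (`date_center`); at the centering
#' date the interaction contributes nothing, so the base cross-basis block
#' alone gives the mid-period exposure-response.
#'
#' @param cb A [build_crossbasis()] matrix.
#' @param deaths Nonnegative integer daily death counts.
#' @param dates Matching `Date` vector.
#' @param time_varying Include the cross-basis-by-date interaction?
#' @param trend_df Degrees of freedom of the long-term trend spline;
#'   default `ceiling(n_years / 10)`.
#' @param season_df Degrees of freedom of the day-of-season spline.
#' @return Object of class `"dlnm_fit"`: coefficients, covariance,
#'   dispersion, block index map (`blocks`), cross-basis metadata, the date
#'   scaling, and fit summaries.
#' @export
fit_dlnm <- function(cb, deaths, dates, time_varying = TRUE,
                     trend_df = NULL, season_df = 4L) {
  stopifnot(nrow(cb) == length(deaths), length(deaths) == length(dates))
  if (any(deaths < 0) || any(deaths != round(deaths)))
    stop("'deaths' must be nonnegative integers")
  dnum <- as.numeric(dates)
  rng <- range(dnum)
  date_center <- mean(rng)
  s <- (dnum - date_center) / diff(rng)          # in [-0.5, 0.5]
  years <- as.integer(strftime(dates, "%Y"))
  n_years <- length(unique(years))
  if (is.null(trend_df)) trend_df <- max(1L, ceiling(n_years / 10))
  dos <- as.integer(dates - as.Date(sprintf("%d-05-01", years))) + 1L
  wd <- factor(strftime(dates, "%u"), levels = as.character(1:7))

  X_cb <- unclass(cb)
  blocks <- list()
  X <- cbind(`(Intercept)` = 1, X_cb)
  blocks$cb <- 1L + seq_len(ncol(X_cb))
  if (time_varying) {
    Xint <- X_cb * s
    colnames(Xint) <- paste0(colnames(X_cb), ":date")
    blocks$interaction <- ncol(X) + seq_len(ncol(Xint))
    X <- cbind(X, Xint)
  }
  Xwd <- stats::model.matrix(~wd)[, -1, drop = FALSE]
  blocks$weekday <- ncol(X) + seq_len(ncol(Xwd))
  X <- cbind(X, Xwd)
  Xtr <- splines::ns(dnum, df = trend_df)
  colnames(Xtr) <- paste0("trend", seq_len(ncol(Xtr)))
  blocks$trend <- ncol(X) + seq_len(ncol(Xtr))
  X <- cbind(X, Xtr)
  Xse <- splines::ns(dos, df = season_df)
  colnames(Xse) <- paste0("season", seq_len(ncol(Xse)))
  blocks$season <- ncol(X) + seq_len(ncol(Xse))
  X <- cbind(X, Xse)

  fit <- stats::glm.fit(X, deaths, family = stats::quasipoisson())
  if (!fit$converged)
    stop("IRLS did not converge; last deviance = ", format(fit$deviance))
  if (anyNA(fit$coefficients)) {
    bad <- names(which(vapply(blocks, function(b)
      anyNA(fit$coefficients[b]), logical(1))))
    stop("rank-deficient design in block(s): ", paste(bad, collapse = ", "))
  }
  mu <- fit$fitted.values
  n <- length(deaths); p <- ncol(X)
  dispersion <- sum((deaths - mu)^2 / mu) / (n - p)
  XtWX <- crossprod(X * sqrt(fit$weights))
  vcov <- dispersion * chol2inv(chol(XtWX))
  dimnames(vcov) <- list(colnames(X), colnames(X))

  structure(
    list(coef = stats::setNames(fit$coefficients, colnames(X)), vcov = vcov,
         dispersion = dispersion, blocks = blocks,
         time_varying = time_varying,
         date_center = as.Date(date_center, origin = "1970-01-01"),
         date_range = rng,
         var_spec = attr(cb, "var_spec"), lag_spec = attr(cb, "lag_spec"),
         max_lag = attr(cb, "max_lag"), lag_basis = attr(cb, "lag_basis"),
         Clag = attr(cb, "Clag"),
         n_obs = n, deviance = fit$deviance,
         trend_df = trend_df, season_df = season_df),
    class = "dlnm_fit")
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat("Time-", if (x$time_varying) "varying" else "constant",
      " quasi-Poisson DLNM: ", x$n_obs, " days, ",
      length(x$coef), " coefficients\n", sep = "")
  cat("  dispersion = ", format(x$dispersion, digits = 4),
      ", max lag = ", x$max_lag, " days\n", sep = "")
  invisible(x)
}

scale_date <- function(fit, date) {
  (as.numeric(date) - mean(fit$date_range)) / diff(fit$date_range)
}

# effective cross-basis coefficient vector(s) at a date
effective_cb_coef <- function(fit, date) {
  th <- fit$coef[fit$blocks$cb]
  if (fit$time_varying)
    th <- th + scale_date(fit, date) * fit$coef[fit$blocks$interaction]
  th
}

#' Overall cumulative exposure-response at a date
#'
#' Sums the fitted lag-specific log relative risks over lags `0..max_lag`
#' for a constant exposure held at each grid temperature, using the
#' effective cross-basis coefficients at `at_date` (base block plus scaled
#' date times interaction block).  The curve is centered at its
#' minimum-mortality temperature, found on a 0.1 degC grid under the
#' constraint that it lies between the stated temperature percentiles.
#' Standard errors come from the delta method applied to the centered
#' contrast.
#'
#' @param fit A [fit_dlnm()] object.
#' @param at_date `Date` at which the time-varying surface is evaluated
#'   (e.g. 1 July of a year).
#' @param temp_grid Temperature grid; default 0.1 degC steps over the basis
#'   boundary.
#' @param mmt_bounds Temperatures `(lo, hi)` constraining the MMT (e.g. the
#'   10th and 90th percentile of summer temperature).
#' @param cen Optional explicit centering temperature; default the MMT.
#' @return Object of class `"exposure_response"`: `temp_grid`,
#'   `cum_log_rr`, `se`, `mmt`, `mmt_bounds`, `at_date`.
#' @export
predict_exposure_response <- function(fit, at_date, temp_grid = NULL,
                                      mmt_bounds = fit$var_spec$boundary,
                                      cen = NULL) {
  bnd <- fit$var_spec$boundary
  if (is.null(temp_grid))
    temp_grid <- seq(bnd[1], bnd[2], by = 0.1)
  if (any(temp_grid < bnd[1] - 1e-8) || any(temp_grid > bnd[2] + 1e-8)) {
    warning("temperature grid outside basis boundary; clamping")
    temp_grid <- clamp(temp_grid, bnd[1], bnd[2])
  }
  Z <- kron_rows(eval_basis(fit$var_spec, temp_grid), fit$Clag)
  th <- effective_cb_coef(fit, at_date)
  u <- drop(Z %*% th)
  mmt <- find_mmt(temp_grid, u, mmt_bounds)
  if (is.null(cen)) cen <- mmt
  Zc <- kron_rows(eval_basis(fit$var_spec, cen), fit$Clag)
  Zd <- Z - Zc[rep(1L, nrow(Z)), , drop = FALSE]
  cum <- drop(Zd %*% th)
  ib <- fit$blocks$cb
  Vb <- fit$vcov[ib, ib]
  if (fit$time_varying) {
    s <- scale_date(fit, at_date)
    ii <- fit$blocks$interaction
    Vb <- Vb + s^2 * fit$vcov[ii, ii] +
      s * (fit$vcov[ib, ii] + fit$vcov[ii, ib])
  }
  se <- sqrt(pmax(rowSums((Zd %*% Vb) * Zd), 0))
  structure(list(at_date = at_date, temp_grid = temp_grid,
                 cum_log_rr = cum, se = se, mmt = mmt,
                 mmt_bounds = mmt_bounds, cen = cen),
            class = "exposure_response")
}

#' Minimum-mortality temperature of a cumulative curve
#'
#' Argmin of the cumulative log relative risk over the grid points lying
#' within `bounds`; ties (including a flat curve, which triggers a warning)
#' are broken toward the lower temperature.
#'
#' @param temp_grid Ascending temperature grid.
#' @param cum_log_rr Curve values on the grid.
#' @param bounds `(lo, hi)` constraint, e.g. whole-period 10th/90th
#'   temperature percentiles.
#' @return The MMT in degC.
#' @export
find_mmt <- function(temp_grid, cum_log_rr, bounds) {
  ok <- temp_grid >= bounds[1] & temp_grid <= bounds[2]
  if (!any(ok)) stop("no grid point within the MMT bounds")
  g <- temp_grid[ok]; u <- cum_log_rr[ok]
  if (diff(range(u)) < 1e-12)
    warning("flat exposure-response curve; returning lowest temperature")
  g[which.min(u)]
}

#' Year-specific minimum-mortality temperatures
#'
#' Evaluates the overall cumulative exposure-response on 1 July of each
#' study year and extracts the constrained MMT.
#'
#' @param fit A [fit_dlnm()] object.
#' @param years Integer vector of years.
#' @param mmt_bounds Constraint passed to [find_mmt()] (typically the
#'   whole-period p10/p90 of summer temperature).
#' @param temp_grid Optional common temperature grid.
#' @return Named numeric vector of MMTs (names = years).
#' @export
annual_mmt <- function(fit, years, mmt_bounds, temp_grid = NULL) {
  vapply(years, function(y) {
    predict_exposure_response(fit, as.Date(sprintf("%d-07-01", y)),
                              temp_grid = temp_grid,
                              mmt_bounds = mmt_bounds)$mmt
  }, numeric(1)) -> m
  stats::setNames(m, years)
}
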