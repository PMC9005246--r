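#' Heat-day threshold definitions
#'
#' Four definitions of a "heat day" (a day whose mean temperature strictly
#' exceeds a threshold): the year-specific minimum-mortality temperature,
#' and the whole-period 95th, 97.5th and 99th percentiles of summer
#' temperature.
#'
#' @param tmean All summer daily temperatures (whole period pooled).
#' @param mmt_by_year Named numeric vector of year-specific MMTs
#'   (from [annual_mmt()]).
#' @param percentiles Whole-period percentiles defining the fixed
#'   thresholds.
#' @return Named list, one element per definition: a threshold vector named
#'   by year (constant across years for percentile definitions).
#' @export
heat_definitions <- function(tmean, mmt_by_year,
                             percentiles = c(0.95, 0.975, 0.99)) {
  yrs <- names(mmt_by_year)
  defs <- list(MMT = mmt_by_year)
  q <- stats::quantile(tmean, percentiles)
  for (k in seq_along(percentiles)) {
    lab <- paste0("p", sub("0+$", "", sub("\\.?0*$", "", format(100 * percentiles[k]))))
    defs[[lab]] <- stats::setNames(rep(q[k], length(yrs)), yrs)
  }
  defs
}

#' Daily backward heat-attributable fractions
#'
#' For each day `t`, the fraction of that day's deaths attributable to its
#' own and the preceding `max_lag` days' temperatures relative to the
#' reference temperature:
#' `AF_t = 1 - exp(-sum_l eta(tmean[t - l], l))`, where `eta` is the fitted
#' lag-specific log relative risk under the effective (date-`t`)
#' coefficients, referenced to the year's MMT.  The lag sum is exactly the
#' day's cross-basis row minus the reference contrast, so the computation is
#' fully vectorized.
#'
#' @param fit A [fit_dlnm()] object.
#' @param cb The [build_crossbasis()] matrix used in the fit.
#' @param dates Matching dates.
#' @param mmt Reference temperature: a scalar, or a vector named by year
#'   for year-specific MMTs.
#' @return Numeric vector of daily AFs (can be negative on cool days).
#' @export
daily_af <- function(fit, cb, dates, mmt) {
  yrs <- strftime(dates, "%Y")
  mmt_t <- if (length(mmt) == 1L) rep(unname(mmt), length(dates))
           else unname(mmt[yrs])
  if (anyNA(mmt_t)) stop("missing MMT for some years")
  X <- unclass(cb)
  thb <- fit$coef[fit$blocks$cb]
  a <- drop(X %*% thb)
  Zm <- kron_rows(eval_basis(fit$var_spec, mmt_t), fit$Clag)
  ref <- drop(Zm %*% thb)
  if (fit$time_varying) {
    s <- scale_date(fit, dates)
    thi <- fit$coef[fit$blocks$interaction]
    a <- a + s * drop(X %*% thi)
    ref <- ref + s * drop(Zm %*% thi)
  }
  1 - exp(-(a - ref))
}

#' Aggregate daily AFs to an annual heat AF
#'
#' The attributable number is the sum of `AF_t * deaths_t` over heat days
#' (strict exceedance of the year's threshold); the attributable fraction
#' divides by the year's total summer deaths.
#'
#' @param af Daily AF vector from [daily_af()].
#' @param deaths,tmean,dates Daily series components.
#' @param thresholds Per-year threshold vector (named by year) or scalar.
#' @param label Heat-definition label stored in the result.
#' @return Data frame: `year`, `heat_def`, `af`, `an`, `n_heat_days`,
#'   `total_deaths`.
#' @export
annual_af <- function(af, deaths, tmean, dates, thresholds, label = "heat") {
  yrs <- strftime(dates, "%Y")
  uy <- sort(unique(yrs))
  thr <- if (length(thresholds) == 1L)
    stats::setNames(rep(unname(thresholds), length(uy)), uy) else thresholds
  out <- lapply(uy, function(y) {
    i <- yrs == y
    tot <- sum(deaths[i])
    if (tot == 0) stop("zero total deaths in year ", y)
    hot <- i & tmean > thr[[y]]
    an <- sum(af[hot] * deaths[hot])
    data.frame(year = as.integer(y), heat_def = label, af = an / tot,
               an = an, n_heat_days = sum(hot), total_deaths = tot)
  })
  do.call(rbind, out)
}

#' Annual AF table across all heat definitions
#'
#' @param fit,cb,dates As in [daily_af()].
#' @param deaths,tmean Daily series components.
#' @param defs Heat definitions from [heat_definitions()]; the MMT element
#'   supplies the AF reference for every definition.
#' @return Stacked data frame from [annual_af()], one block per definition.
#' @export
af_table <- function(fit, cb, dates, deaths, tmean, defs) {
  af <- daily_af(fit, cb, dates, defs$MMT)
  do.call(rbind, lapply(names(defs), function(lab)
    annual_af(af, deaths, tmean, dates, defs[[lab]], lab)))
}

#' Empirical confidence intervals by coefficient simulation
#'
#' Draws `n_sim` cross-basis (and interaction) coefficient vectors from the
#' multivariate normal approximation `N(coef, vcov)` and, for each draw,
#' recomputes the year-specific constrained MMTs and the annual AFs under
#' every heat definition (the MMT constraint and the MMT-based heat-day set
#' are re-solved per draw).  Percentile 2.5/97.5 bounds are reported per
#' year, for the period-average AF of each definition, and for the MMTs.
#'
#' @param fit A [fit_dlnm()] object.
#' @param cb,dates,deaths,tmean Daily data as in [af_table()].
#' @param mmt_bounds `(lo, hi)` MMT constraint (p10/p90 of `tmean` if
#'   omitted).
#' @param percentiles Fixed-threshold heat percentiles.
#' @param n_sim Number of coefficient draws (warning below 100).
#' @param seed Integer seed.
#' @param temp_grid MMT search grid (default 0.1 degC steps over the basis
#'   boundary).
#' @return List: `per_year` (year, heat_def, eci_lo, eci_hi), `average`
#'   (heat_def, eci_lo, eci_hi), `mmt` (year, eci_lo, eci_hi), and the
#'   matrix of period-average AF draws in `average_draws`.
#' @export
empirical_ci <- function(fit, cb, dates, deaths, tmean,
                         mmt_bounds = stats::quantile(tmean, c(0.1, 0.9)),
                         percentiles = c(0.95, 0.975, 0.99),
                         n_sim = 1000L, seed = 1L, temp_grid = NULL) {
  if (n_sim < 100) warning("n_sim < 100 gives unstable percentile bounds")
  ib <- fit$blocks$cb
  ii <- fit$blocks$interaction
  sel <- c(ib, ii)
  V <- fit$vcov[sel, sel]
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    warning("covariance not positive semidefinite; flooring eigenvalues at 0")
  }
  lam <- pmax(ev$values, 0)
  Vfl <- ev$vectors %*% (lam * t(ev$vectors))
  set.seed(seed)
  draws <- MASS::mvrnorm(n_sim, mu = fit$coef[sel], Sigma = Vfl, tol = 1e-6)
  vp <- length(ib)
  Tb <- t(draws[, seq_len(vp), drop = FALSE])                  # vp x S
  Ti <- if (fit$time_varying) t(draws[, vp + seq_len(vp), drop = FALSE])

  bnd <- fit$var_spec$boundary
  if (is.null(temp_grid)) temp_grid <- seq(bnd[1], bnd[2], by = 0.1)
  ok <- temp_grid >= mmt_bounds[1] & temp_grid <= mmt_bounds[2]
  grid_c <- temp_grid[ok]
  Zg <- kron_rows(eval_basis(fit$var_spec, grid_c), fit$Clag)
  G1 <- Zg %*% Tb                                              # g x S
  G2 <- if (fit$time_varying) Zg %*% Ti

  X <- unclass(cb)
  A <- X %*% Tb                                                # n x S
  s_t <- scale_date(fit, dates)
  if (fit$time_varying) A <- A + s_t * (X %*% Ti)

  yrs <- strftime(dates, "%Y")
  uy <- sort(unique(yrs))
  qfix <- stats::quantile(tmean, percentiles)
  labs <- names(heat_definitions(tmean, stats::setNames(numeric(length(uy)), uy),
                                 percentiles))
  n_def <- length(labs)
  af_draw <- array(NA_real_, c(length(uy), n_def, n_sim),
                   dimnames = list(uy, labs, NULL))
  mmt_draw <- matrix(NA_real_, length(uy), n_sim, dimnames = list(uy, NULL))

  Clag <- fit$Clag
  for (k in seq_along(uy)) {
    y <- uy[k]
    s_y <- scale_date(fit, as.Date(sprintf("%s-07-01", y)))
    U <- if (fit$time_varying) G1 + s_y * G2 else G1
    mmt_k <- grid_c[max.col(-t(U), ties.method = "first")]
    mmt_draw[k, ] <- mmt_k
    i <- which(yrs == y)
    # reference contrast per draw at this year's MMT, day-date coefficients
    Zm <- kron_rows(eval_basis(fit$var_spec, mmt_k), Clag)     # S x vp
    refb <- rowSums(Zm * t(Tb))                                # S
    refi <- if (fit$time_varying) rowSums(Zm * t(Ti)) else 0
    eta <- A[i, , drop = FALSE] -
      (matrix(refb, length(i), n_sim, byrow = TRUE) +
         outer(s_t[i], if (fit$time_varying) refi else rep(0, n_sim)))
    afd <- 1 - exp(-eta)                                       # n_i x S
    d_i <- deaths[i]; x_i <- tmean[i]; tot <- sum(d_i)
    for (j in seq_len(n_def)) {
      mask <- if (labs[j] == "MMT") outer(x_i, mmt_k, ">")
              else matrix(x_i > qfix[j - 1L], length(i), n_sim)
      af_draw[k, j, ] <- colSums(mask * afd * d_i) / tot
    }
  }
  avg <- apply(af_draw, c(2, 3), mean)                         # def x S
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  per_year <- do.call(rbind, lapply(seq_along(uy), function(k)
    do.call(rbind, lapply(seq_len(n_def), function(j) {
      b <- qs(af_draw[k, j, ])
      data.frame(year = as.integer(uy[k]), heat_def = labs[j],
                 eci_lo = b[1], eci_hi = b[2])
    }))))
  average <- do.call(rbind, lapply(seq_len(n_def), function(j) {
    b <- qs(avg[j, ])
    data.frame(heat_def = labs[j], eci_lo = b[1], eci_hi = b[2])
  }))
  mmt_ci <- do.call(rbind, lapply(seq_along(uy), function(k) {
    b <- qs(mmt_draw[k, ])
    data.frame(year = as.integer(uy[k]), eci_lo = b[1], eci_hi = b[2])
  }))
  list(per_year = per_year, average = average, mmt = mmt_ci,
       average_draws = avg)
}

#' Run stage 1 end to end on a daily series
#'
#' Builds the cross-basis, fits the time-varying DLNM, extracts
#' year-specific MMTs (1 July curves, constrained to the whole-period
#' p10-p90 temperature range) and computes the annual AF table under all
#' four heat definitions.
#'
#' @param series Data frame `date`, `deaths`, `tmean` (May-September days).
#' @param max_lag Maximum lag, days.
#' @param mmt_percentiles Percentile constraint for the MMT.
#' @param heat_percentiles Whole-period heat-day percentiles.
#' @param time_varying Include the date interaction.
#' @param trend_df,season_df Passed to [fit_dlnm()].
#' @return List of class `"stage1_result"`: `fit`, `cb`, `mmt`,
#'   `mmt_bounds`, `defs`, `af` (annual AF table), `series`.
#' @export
stage1_af <- function(series, max_lag = 10L, mmt_percentiles = c(0.1, 0.9),
                      heat_percentiles = c(0.95, 0.975, 0.99),
                      time_varying = TRUE, trend_df = NULL, season_df = 4L) {
  stopifnot(all(c("date", "deaths", "tmean") %in% names(series)))
  series <- series[order(series$date), ]
  cb <- build_crossbasis(series$tmean, series$date, max_lag = max_lag)
  fit <- fit_dlnm(cb, series$deaths, series$date,
                  time_varying = time_varying,
                  trend_df = trend_df, season_df = season_df)
  years <- sort(unique(as.integer(strftime(series$date, "%Y"))))
  mmt_bounds <- unname(stats::quantile(series$tmean, mmt_percentiles))
  mmt <- annual_mmt(fit, years, mmt_bounds)
  defs <- heat_definitions(series$tmean, mmt, heat_percentiles)
  af <- af_table(fit, cb, series$date, series$deaths, series$tmean, defs)
  structure(list(fit = fit, cb = cb, mmt = mmt, mmt_bounds = mmt_bounds,
                 defs = defs, af = af, series = series),
            class = "stage1_result")
}
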