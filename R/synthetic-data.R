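#' Ground truth for synthetic heat-mortality data
#'
#' Bundles the true exposure-lag-response surface and the parameters linking
#' a climate index to summer heat, so simulated data have a known answer for
#' both analysis stages.  The default surface is J-shaped in temperature: a
#' linear "hockey stick" of slope `heat_slope` above the minimum-mortality
#' temperature `mmt_true` (with a quadratic shoulder of width `smooth_delta`
#' so the surface is continuously differentiable) and a mild quadratic cold
#' rise below it, so the risk minimum is identified.  The cumulative curve
#' is distributed over lags `0..max_lag` with geometric decay `lag_decay`
#' and equals 0 at `mmt_true` by construction.  Defaults are calibrated so
#' the true annual AF above the MMT is in the 2-3% range typical of
#' city-scale summer heat mortality.
#'
#' @param mmt_true True minimum-mortality temperature (degC).
#' @param heat_slope Cumulative log-RR per degC above `mmt_true`.
#' @param cold_curv Quadratic cold coefficient (log-RR per degC^2 below
#'   `mmt_true`).
#' @param smooth_delta Width (degC) of the quadratic shoulder joining the
#'   flat minimum to the linear heat slope.
#' @param lag_decay Geometric decay ratio of the lag weights.
#' @param max_lag Maximum lag in days over which risk is distributed.
#' @param active_index Name of the index driving summer heat, or `NULL` for
#'   no climate signal.
#' @param beta_true Function of lag in months (0..16) giving the true
#'   stage-2 functional coefficient; defaults to a half-cosine supported on
#'   lags 0-5 when an index is active, identically 0 otherwise.
#' @param overdispersion Variance/mean ratio of daily death counts (>= 1;
#'   1 gives Poisson counts).
#' @return Object of class `"synthetic_truth"` with elements including
#'   `rr_surface(x, l)`, the marginal cumulative curve `cum_curve(x)` and
#'   the lag weights `lag_weights`.
#' @export
synthetic_truth <- function(mmt_true = 18, heat_slope = 0.02,
                            cold_curv = 0.003, smooth_delta = 3,
                            lag_decay = 0.6,
                            max_lag = 10L, active_index = "AMO",
                            beta_true = NULL, overdispersion = 1.2) {
  stopifnot(overdispersion >= 1, heat_slope >= 0, cold_curv >= 0,
            smooth_delta > 0)
  w <- lag_decay^(0:max_lag)
  w <- w / sum(w)
  cum_curve <- function(x) {
    u <- x - mmt_true
    ifelse(u > smooth_delta, heat_slope * (u - smooth_delta / 2),
           ifelse(u > 0, heat_slope * u^2 / (2 * smooth_delta),
                  cold_curv * u^2))
  }
  rr_surface <- function(x, l) cum_curve(x) * w[l + 1L]
  if (is.null(beta_true)) {
    beta_true <- if (is.null(active_index)) {
      function(l) rep(0, length(l))
    } else {
      function(l) ifelse(l <= 5, 0.01 * cos(pi * l / 10), 0)
    }
  }
  structure(
    list(mmt_true = mmt_true, heat_slope = heat_slope, cold_curv = cold_curv,
         smooth_delta = smooth_delta,
         lag_decay = lag_decay, max_lag = as.integer(max_lag),
         lag_weights = w, cum_curve = cum_curve, rr_surface = rr_surface,
         active_index = active_index, beta_true = beta_true,
         overdispersion = overdispersion),
    class = "synthetic_truth")
}

default_index_names <- function(n) {
  base <- c("AMO", "SOI", "AO", "NAO", "ONI", "PDO", "PNA")
  if (n <= 7) base[seq_len(n)] else c(base, paste0("IDX", 8:n))[seq_len(n)]
}

#' Simulate a monthly climate-index panel
#'
#' Generates `n_indices` mutually independent stationary AR(1) monthly
#' series, standardized to zero mean and unit variance, covering January of
#' `min(years) - 1` through December of `max(years)` (one year of history
#' before the study so 16-month lag curves are available for the first
#' study year).  The "active" index is given a slow dynamic (lag-1
#' autocorrelation `rho_active`, as for multidecadal sea-surface-temperature
#' indices); the others decorrelate faster.
#'
#' @param years Integer vector of study years.
#' @param n_indices Number of indices (default 7: AMO, SOI, AO, NAO, ONI,
#'   PDO, PNA).
#' @param active Name of the active index (must be among the generated
#'   names), or `NULL`.
#' @param rho_active,rho_other Lag-1 autocorrelations.
#' @param seed Integer seed.
#' @return A data frame with columns `year`, `month` and one column per
#'   index; attribute `index_names`.
#' @export
simulate_indices <- function(years, n_indices = 7L, active = "AMO",
                             rho_active = 0.9, rho_other = 0.3, seed = 1L) {
  stopifnot(length(years) > 0, n_indices >= 1)
  years <- sort(unique(as.integer(years)))
  names_ <- default_index_names(n_indices)
  if (!is.null(active) && !active %in% names_)
    stop("active index '", active, "' is not among the generated indices")
  set.seed(seed)
  yy <- seq(min(years) - 1L, max(years))
  grid <- expand.grid(month = 1:12, year = yy)[, c("year", "month")]
  n <- nrow(grid)
  panel <- grid
  for (nm in names_) {
    rho <- if (!is.null(active) && nm == active) rho_active else rho_other
    e <- stats::rnorm(n, sd = sqrt(1 - rho^2))
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    for (t in 2:n) z[t] <- rho * z[t - 1] + e[t]
    panel[[nm]] <- z
  }
  attr(panel, "index_names") <- names_
  panel
}

season_days <- function(year, burnin = 10L) {
  first <- as.Date(sprintf("%d-05-01", year))
  seq(first - burnin, as.Date(sprintf("%d-09-30", year)), by = "day")
}

#' Simulate daily summer temperature
#'
#' Daily mean temperature for May-September of each study year (plus a
#' 10-day pre-season burn-in so every season day has a full lag history):
#' a sinusoidal annual cycle, stationary AR(1) daily noise, and a uniform
#' summer shift of `gamma` degC per standard deviation of the active
#' index's January-May mean that year.  With `gamma = 0` summers are
#' unrelated to the index panel.
#'
#' @param panel Index panel from [simulate_indices()].
#' @param truth A [synthetic_truth()] (supplies the active index name).
#' @param years Study years to simulate (must be covered by `panel`).
#' @param gamma Summer warming per SD of the active index (degC).
#' @param t_mid,t_amp,peak_doy Annual cycle: mean level, amplitude and peak
#'   day of year of `t_mid + t_amp * cos(2*pi*(doy - peak_doy)/365)`.
#' @param ar_rho,ar_sd Daily AR(1) noise: autocorrelation and stationary SD.
#' @param seed Integer seed.
#' @return Data frame `date`, `tmean`, `burnin` (logical: pre-season rows,
#'   used only to provide lag history).
#' @export
simulate_temperature <- function(panel, truth, years, gamma = 1.5,
                                 t_mid = 8, t_amp = 14, peak_doy = 201,
                                 ar_rho = 0.7, ar_sd = 2.5, seed = 1L) {
  years <- sort(unique(as.integer(years)))
  if (!all(years %in% panel$year))
    stop("index panel does not cover all requested years")
  active <- truth$active_index
  if (!is.null(active) && !active %in% names(panel))
    stop("active index '", active, "' not found in panel")
  set.seed(seed)
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    dates <- season_days(y)
    doy <- as.integer(strftime(dates, "%j"))
    seasonal <- t_mid + t_amp * cos(2 * pi * (doy - peak_doy) / 365)
    shift <- 0
    if (!is.null(active) && gamma != 0) {
      jm <- panel[[active]][panel$year == y & panel$month <= 5]
      shift <- gamma * mean(jm)
    }
    n <- length(dates)
    e <- stats::rnorm(n, sd = ar_sd * sqrt(1 - ar_rho^2))
    z <- numeric(n)
    z[1] <- stats::rnorm(1, sd = ar_sd)
    for (t in 2:n) z[t] <- ar_rho * z[t - 1] + e[t]
    out[[k]] <- data.frame(date = dates, tmean = seasonal + shift + z,
                           burnin = strftime(dates, "%m") == "04")
  }
  do.call(rbind, out)
}

#' Simulate daily death counts
#'
#' Draws daily all-cause death counts from a negative-binomial distribution
#' with mean `mu_t` and variance `overdispersion * mu_t` (Poisson when the
#' overdispersion is 1), where `log mu_t` combines a baseline level, a slow
#' linear trend, within-season seasonality, a day-of-week effect and the
#' cumulative lagged temperature effect of `truth$rr_surface` evaluated over
#' the preceding `max_lag` days (burn-in rows supply the history at season
#' starts).  Burn-in rows are dropped from the output.
#'
#' @param temps Output of [simulate_temperature()].
#' @param truth A [synthetic_truth()].
#' @param baseline Expected deaths/day at the reference level (> 0).
#' @param trend_slope Log-linear trend per year.
#' @param seas_amp Amplitude of the annual mortality cycle (peaking in
#'   winter, so midsummer baseline mortality is lowest).
#' @param weekday_eff Length-7 log-scale day-of-week effects (Mon..Sun).
#' @param seed Integer seed.
#' @return Data frame `date`, `deaths`, `tmean` (season days only), with the
#'   true expected counts in attribute `mu` and the no-excess expectation
#'   (risk surface set to zero) in attribute `mu0`.
#' @export
simulate_mortality <- function(temps, truth, baseline = 60,
                               trend_slope = 0.002, seas_amp = 0.08,
                               weekday_eff = c(0, -0.005, -0.01, -0.005,
                                               0, 0.01, 0.015),
                               seed = 1L) {
  if (baseline <= 0) stop("'baseline' must be positive")
  stopifnot(length(weekday_eff) == 7)
  set.seed(seed)
  L <- truth$max_lag
  yr <- as.integer(strftime(temps$date, "%Y"))
  pieces <- split(seq_len(nrow(temps)), yr)
  mid_year <- mean(range(yr))
  res <- vector("list", length(pieces))
  for (k in seq_along(pieces)) {
    idx <- pieces[[k]]
    x <- temps$tmean[idx]
    keep <- !temps$burnin[idx]
    if (sum(!keep) < L) stop("need at least max_lag burn-in days per season")
    cum <- numeric(length(x))
    for (l in 0:L) {
      xl <- c(rep(x[1], l), x[seq_len(length(x) - l)])
      cum <- cum + truth$rr_surface(xl, l)
    }
    dates <- temps$date[idx]
    doy <- as.integer(strftime(dates, "%j"))
    wd <- as.integer(strftime(dates, "%u"))
    base_log <- log(baseline) + trend_slope * (yr[idx] - mid_year) +
      seas_amp * cos(2 * pi * (doy - 15) / 365) + weekday_eff[wd]
    mu <- exp(base_log + cum)
    mu0 <- exp(base_log)
    if (any(!is.finite(mu)) || any(mu > 1e8))
      stop("expected death count overflow; check the risk surface")
    phi <- truth$overdispersion
    deaths <- if (phi > 1) {
      stats::rnbinom(length(mu), mu = mu, size = mu / (phi - 1))
    } else {
      stats::rpois(length(mu), mu)
    }
    res[[k]] <- data.frame(date = dates, deaths = deaths, tmean = x,
                           mu = mu, mu0 = mu0)[keep, ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out[, c("date", "deaths", "tmean")],
            mu = out$mu, mu0 = out$mu0)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_indices()],
#' [simulate_temperature()] and [simulate_mortality()] with sub-seeds
#' derived from `seed`.
#'
#' @param years Study years (default 1981:2018).
#' @param truth A [synthetic_truth()].
#' @param gamma Index-to-summer-heat link (degC per SD), see
#'   [simulate_temperature()].
#' @param baseline Baseline deaths/day.
#' @param seed Integer master seed.
#' @param ... Passed on to [simulate_mortality()].
#' @return List `series` (date, deaths, tmean), `panel`, `truth`, `temps`
#'   (including burn-in rows).
#' @export
simulate_study <- function(years = 1981:2018, truth = synthetic_truth(),
                           gamma = 1.5, baseline = 60, seed = 1L, ...) {
  panel <- simulate_indices(years, active = truth$active_index,
                            seed = seed)
  temps <- simulate_temperature(panel, truth, years, gamma = gamma,
                                seed = seed + 1000L)
  series <- simulate_mortality(temps, truth, baseline = baseline,
                               seed = seed + 2000L, ...)
  list(series = series, panel = panel, truth = truth, temps = temps)
}

#' Write/read daily series and index panels as CSV
#'
#' Daily series use ISO-8601 dates, one row per day; panels one row per
#' month.  [write_synthetic_truth()] stores the scalar ground-truth
#' parameters as a JSON sidecar.
#'
#' @param x Object to write.
#' @param path File path.
#' @name heatlag-io
#' @return The input, invisibly (writers); a data frame (readers).
NULL

#' @rdname heatlag-io
#' @export
write_daily_series <- function(x, path) {
  utils::write.csv(data.frame(date = format(x$date, "%Y-%m-%d"),
                              deaths = x$deaths, tmean = x$tmean),
                   path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname heatlag-io
#' @export
read_daily_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "deaths", "tmean") %in% names(x)))
  x$date <- as.Date(x$date)
  if (anyDuplicated(x$date)) stop("duplicate dates in daily series")
  if (any(x$deaths < 0)) stop("negative death counts")
  x[order(x$date), ]
}

#' @rdname heatlag-io
#' @export
write_index_panel <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname heatlag-io
#' @export
read_index_panel <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "month") %in% names(x)))
  attr(x, "index_names") <- setdiff(names(x), c("year", "month"))
  x
}

#' @rdname heatlag-io
#' @export
write_synthetic_truth <- function(x, path) {
  jsonlite::write_json(
    x[c("mmt_true", "heat_slope", "cold_curv", "smooth_delta", "lag_decay",
        "max_lag", "active_index", "overdispersion")],
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(x)
}
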