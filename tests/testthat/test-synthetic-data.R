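test_that("index panel has full coverage, is standardized and reproducible", {
  p <- simulate_indices(1981:2020, n_indices = 7, active = "AMO", seed = 3)
  expect_equal(attr(p, "index_names"),
               c("AMO", "SOI", "AO", "NAO", "ONI", "PDO", "PNA"))
  expect_gte(nrow(p), 480L)
  expect_equal(nrow(p), 12L * (2020 - 1980 + 1))       # history year included
  expect_identical(p, simulate_indices(1981:2020, n_indices = 7,
                                       active = "AMO", seed = 3))
  expect_error(simulate_indices(1981:1990, active = "NOPE"), "NOPE")
})

test_that("active index shows the configured lag-1 autocorrelation", {
  p <- simulate_indices(1:500, active = "AMO", rho_active = 0.9,
                        rho_other = 0.3, seed = 11)
  r1 <- function(z) cor(z[-1], z[-length(z)])
  expect_lt(abs(r1(p$AMO) - 0.9), 0.05)
  expect_lt(abs(r1(p$SOI) - 0.3), 0.05)
  expect_lt(abs(mean(p$AMO)), 0.1)
  expect_lt(abs(sd(p$AMO) - 1), 0.1)
})

test_that("summer temperature responds linearly to the active index", {
  truth <- synthetic_truth()
  years <- 1901:2000
  panel <- simulate_indices(years, seed = 5)
  # gamma = 0: summers unrelated to the index
  t0 <- simulate_temperature(panel, truth, years, gamma = 0, seed = 9)
  sm <- tapply(t0$tmean[!t0$burnin],
               strftime(t0$date[!t0$burnin], "%Y"), mean)
  jm <- vapply(years, function(y)
    mean(panel$AMO[panel$year == y & panel$month <= 5]), numeric(1))
  expect_lt(abs(cor(as.numeric(sm), jm)), 0.2)
  # additive construction: +2 SD of the index shifts a summer by gamma * 2
  panel2 <- panel
  panel2$AMO[panel2$year == 1950] <- panel2$AMO[panel2$year == 1950] + 2
  t1 <- simulate_temperature(panel, truth, years, gamma = 1.5, seed = 9)
  t2 <- simulate_temperature(panel2, truth, years, gamma = 1.5, seed = 9)
  d <- t2$tmean[strftime(t2$date, "%Y") == "1950"] -
    t1$tmean[strftime(t1$date, "%Y") == "1950"]
  expect_equal(unique(round(d, 10)), 3)
  # determinism
  expect_identical(t1, simulate_temperature(panel, truth, years,
                                            gamma = 1.5, seed = 9))
})

test_that("death counts match the constructed expectation and noise model", {
  years <- 1801:2000
  panel <- simulate_indices(years, seed = 2)
  # null risk surface: realized totals match the baseline construction
  truth0 <- synthetic_truth(heat_slope = 0, cold_curv = 0)
  temps <- simulate_temperature(panel, truth0, years, seed = 4)
  s0 <- simulate_mortality(temps, truth0, baseline = 20, seed = 6)
  expect_lt(abs(sum(s0$deaths) / sum(attr(s0, "mu0")) - 1), 0.02)
  expect_identical(attr(s0, "mu"), attr(s0, "mu0"))
  # overdispersion 1.2 vs Poisson variance/mean ratios
  r_od <- function(s) {
    z <- (s$deaths - attr(s, "mu")) / sqrt(attr(s, "mu"))
    mean(z^2)
  }
  expect_lt(abs(r_od(s0) - 1.2), 0.05)
  truth_p <- synthetic_truth(heat_slope = 0, cold_curv = 0,
                             overdispersion = 1)
  sp <- simulate_mortality(temps, truth_p, baseline = 20, seed = 6)
  expect_lt(abs(r_od(sp) - 1), 0.05)
  expect_error(simulate_mortality(temps, truth0, baseline = -1), "positive")
})

test_that("a single-day heat pulse raises expectations by the lag surface", {
  truth <- synthetic_truth()
  dates <- heatlag:::season_days(2000)
  base <- data.frame(date = dates, tmean = truth$mmt_true,
                     burnin = strftime(dates, "%m") == "04")
  pulse <- base
  k <- which(!pulse$burnin)[60]          # 60th season day
  pulse$tmean[k] <- truth$mmt_true + 5
  mb <- attr(simulate_mortality(base, truth, baseline = 50, seed = 1), "mu")
  mp <- attr(simulate_mortality(pulse, truth, baseline = 50, seed = 1), "mu")
  for (l in 0:truth$max_lag) {
    expected <- exp(truth$cum_curve(truth$mmt_true + 5) *
                      truth$lag_weights[l + 1])
    expect_equal(mp[60 + l] / mb[60 + l], expected)
  }
  # beyond the maximum lag the pulse has no effect
  expect_equal(mp[60 + truth$max_lag + 1], mb[60 + truth$max_lag + 1])
})

test_that("truth surface invariants hold", {
  truth <- synthetic_truth()
  cum <- sum(vapply(0:truth$max_lag, function(l)
    truth$rr_surface(truth$mmt_true, l), numeric(1)))
  expect_equal(cum, 0)
  g <- seq(0, 30, by = 0.1)
  expect_equal(g[which.min(truth$cum_curve(g))], truth$mmt_true)
  none <- synthetic_truth(active_index = NULL)
  expect_true(all(none$beta_true(0:16) == 0))
  expect_equal(sum(truth$lag_weights), 1)
})

test_that("daily series round-trips through CSV with validation", {
  sim <- small_study(years = 2001:2003, seed = 8)
  f <- tempfile(fileext = ".csv")
  write_daily_series(sim$series, f)
  back <- read_daily_series(f)
  expect_equal(back$deaths, sim$series$deaths)
  expect_equal(back$tmean, sim$series$tmean, tolerance = 1e-12)
  expect_s3_class(back$date, "Date")
  fp <- tempfile(fileext = ".csv")
  write_index_panel(sim$panel, fp)
  expect_equal(attr(read_index_panel(fp), "index_names"),
               attr(sim$panel, "index_names"))
  ft <- tempfile(fileext = ".json")
  write_synthetic_truth(sim$truth, ft)
  js <- jsonlite::read_json(ft)
  expect_equal(js$mmt_true, sim$truth$mmt_true)
})
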