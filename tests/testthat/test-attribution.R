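test_that("daily AF identities: reference zero and closed forms", {
  sim <- small_study(seed = 10)
  s1 <- stage1_af(sim$series)
  # constant series at the reference temperature has AF exactly 0
  dates <- sim$series$date[1:40]
  cb_ref <- build_crossbasis(rep(17, 40), dates,
                             var_spec = s1$fit$var_spec,
                             lag_spec = s1$fit$lag_spec)
  af0 <- daily_af(s1$fit, cb_ref, dates, mmt = 17)
  expect_lt(max(abs(af0)), 1e-12)
})

test_that("daily AF matches a direct basis-evaluation oracle on a toy", {
  sim <- small_study(seed = 11)
  s1 <- stage1_af(sim$series)
  fit <- s1$fit
  days <- 40:59                              # 20-day window, full history
  mmt_y <- s1$defs$MMT
  af <- daily_af(fit, s1$cb, sim$series$date, mmt_y)
  v <- n_basis(fit$var_spec)
  for (t in days) {
    d <- sim$series$date[t]
    th <- matrix(heatlag:::effective_cb_coef(fit, d), nrow = v, byrow = TRUE)
    mmt <- mmt_y[[strftime(d, "%Y")]]
    eta <- 0
    for (l in 0:fit$max_lag) {
      xl <- sim$series$tmean[t - l]
      eta <- eta + drop((eval_basis(fit$var_spec, xl) -
                           eval_basis(fit$var_spec, mmt)) %*%
                          th %*% fit$lag_basis[l + 1, ])
    }
    expect_equal(af[t], 1 - exp(-eta), tolerance = 1e-10)
  }
})

test_that("annual aggregation arithmetic and linearity", {
  dates <- seq(as.Date("2001-05-01"), by = "day", length.out = 153)
  deaths <- rep(10, 153); deaths[1] <- 10
  tmean <- rep(15, 153); tmean[50] <- 25
  af <- rep(0, 153); af[50] <- 0.1
  out <- annual_af(af, deaths, tmean, dates, thresholds = 20, label = "x")
  expect_equal(out$af, 0.1 * 10 / sum(deaths))
  expect_equal(out$n_heat_days, 1L)
  # no heat days
  out0 <- annual_af(af, deaths, tmean, dates, thresholds = 30, label = "x")
  expect_equal(out0$af, 0)
  expect_equal(out0$n_heat_days, 0L)
  # AN is additive over disjoint heat-day sets
  tmean2 <- tmean; tmean2[60] <- 25; af2 <- af; af2[60] <- 0.05
  both <- annual_af(af2, deaths, tmean2, dates, 20, "x")$an
  only50 <- annual_af(af2 * (seq_len(153) == 50), deaths, tmean2, dates, 20, "x")$an
  only60 <- annual_af(af2 * (seq_len(153) == 60), deaths, tmean2, dates, 20, "x")$an
  expect_equal(both, only50 + only60)
  expect_error(annual_af(af, deaths * 0, tmean, dates, 20), "zero total")
})

test_that("AF threshold monotonicity when thresholds exceed the MMT", {
  sim <- small_study(seed = 12, years = 2001:2010)
  s1 <- stage1_af(sim$series)
  wide <- reshape(s1$af[, c("year", "heat_def", "af")],
                  direction = "wide", idvar = "year", timevar = "heat_def")
  ok <- sapply(seq_len(nrow(wide)), function(i) {
    thr_above <- all(s1$defs$p95 > s1$defs$MMT[as.character(wide$year[i])])
    !thr_above || (wide$af.p99[i] <= wide$af.p97.5[i] + 1e-12 &&
                     wide$af.p97.5[i] <= wide$af.p95[i] + 1e-12)
  })
  expect_true(all(ok))
  # AF never exceeds 1
  af <- daily_af(s1$fit, s1$cb, sim$series$date, s1$defs$MMT)
  expect_true(all(af <= 1))
})

test_that("empirical CIs are deterministic and collapse as vcov -> 0", {
  sim <- small_study(seed = 13)
  s1 <- stage1_af(sim$series)
  args <- list(s1$fit, s1$cb, sim$series$date, sim$series$deaths,
               sim$series$tmean, mmt_bounds = s1$mmt_bounds, n_sim = 150L)
  e1 <- do.call(empirical_ci, c(args, seed = 99))
  e2 <- do.call(empirical_ci, c(args, seed = 99))
  expect_identical(e1, e2)
  expect_warning(do.call(empirical_ci, c(args[1:5],
                                         list(n_sim = 50L, seed = 1))),
                 "unstable")
  # degenerate normal: bounds equal the point estimate pipeline
  fit0 <- s1$fit
  fit0$vcov[] <- 0
  e0 <- empirical_ci(fit0, s1$cb, sim$series$date, sim$series$deaths,
                     sim$series$tmean, mmt_bounds = s1$mmt_bounds,
                     n_sim = 120L, seed = 5)
  expect_equal(e0$average$eci_lo, e0$average$eci_hi, tolerance = 1e-12)
  af_point <- tapply(s1$af$af, s1$af$heat_def, mean)
  expect_equal(e0$average$eci_lo[e0$average$heat_def == "MMT"],
               unname(af_point["MMT"]), tolerance = 1e-10)
})

test_that("null-risk synthetic data give AF estimates centered on zero", {
  # under a flat true surface the MMT is undefined, so AFs are referenced
  # to a fixed temperature: any systematic departure from zero would be
  # spurious attribution (referencing to the fitted curve's own minimum
  # would instead be nonnegative by construction)
  truth0 <- synthetic_truth(heat_slope = 0, cold_curv = 0)
  afs <- vapply(1:50, function(r) {
    sim <- small_study(seed = 500 + r, truth = truth0, years = 2001:2012)
    s1 <- stage1_af(sim$series)
    af <- daily_af(s1$fit, s1$cb, sim$series$date, mmt = 18)
    out <- annual_af(af, sim$series$deaths, sim$series$tmean,
                     sim$series$date, thresholds = 18, label = "fixed")
    mean(out$af)
  }, numeric(1))
  expect_lt(abs(mean(afs)), 2 * sd(afs) / sqrt(length(afs)))
})
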