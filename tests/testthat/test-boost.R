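test_that("functional design has the documented layout and quadrature", {
  panel <- simulate_indices(1981:2018, seed = 1)
  af <- data.frame(year = 1981:2018, af = rnorm(38, 0.02, 0.005))
  des <- build_functional_design(af, panel)
  expect_equal(dim(des$curves), c(38L, 7L, 17L))
  # lag 0 = May of the AF year; lag 16 = January of the previous year
  raw <- function(y, m) panel$AMO[panel$year == y & panel$month == m]
  z <- (des$curves[, "AMO", ] * des$standardization$sd[1]) +
    des$standardization$mean[1]
  k <- which(des$years == 2000)
  expect_equal(unname(z[k, 1]), raw(2000, 5))
  expect_equal(unname(z[k, 17]), raw(1999, 1))
  # trapezoid rule is exact on constants: integral of c over [0, 16]
  expect_equal(sum(des$quad_weights * rep(3, 17)), 3 * 16)
  # standardized cells
  expect_lt(max(abs(apply(des$curves, 2, mean))), 1e-12)
  expect_lt(max(abs(apply(des$curves, 2, sd) - 1)), 1e-12)
  # missing months are reported
  p2 <- panel[!(panel$year == 1999 & panel$month == 3), ]
  expect_error(build_functional_design(af, p2), "AMO: 1999-3")
})

test_that("base learners hit their common effective df", {
  des <- stage2_toy(seed = 2)$design
  for (l in c(default_learners(des),
              list(scalar_learner(rnorm(38))))) {
    pr <- heatlag:::prep_learner(l, 1:38)
    expect_lt(abs(sum(diag(pr$H)) - l$df_target), 0.01)
  }
  expect_error(heatlag:::prep_learner(
    functional_learner(des, 1, df_target = 50), 1:38), "unpenalized")
})

test_that("year learner: 24 columns, exact on linear trends, ridge oracle", {
  des <- stage2_toy(seed = 3)$design
  yl <- year_learner(des)
  expect_equal(ncol(yl$Z), 24L)
  lin <- 0.01 + 0.0005 * (des$years - 1980)
  pr <- heatlag:::prep_learner(yl, 1:38)
  expect_lt(max(abs(lin - pr$H %*% lin)), 1e-10)
  # penalized solve matches the direct normal-equations oracle
  set.seed(4); y <- rnorm(38)
  cf <- drop(pr$A %*% y)
  oracle <- solve(crossprod(yl$Z) + pr$lambda * yl$P, crossprod(yl$Z, y))
  expect_equal(cf, drop(oracle), tolerance = 1e-10)
  expect_warning(year_learner(list(years = 1981:1995,
                                   curves = array(0, c(15, 1, 17)))),
                 "reducing")
})

test_that("functional learner reduces to and recovers known structures", {
  toy <- stage2_toy(seed = 5)
  des <- toy$design
  # constant-only coefficient basis: learner equals regression on the
  # curve integral
  Zint <- rowSums(des$curves[, 1, ] *
                    matrix(des$quad_weights, 38, 17, byrow = TRUE))
  lc <- heatlag:::new_learner("int", "functional",
                              matrix(Zint, ncol = 1),
                              matrix(0, 1, 1), 1,
                              meta = list(B_grid = matrix(1, 17, 1)))
  pr <- heatlag:::prep_learner(lc, 1:38)
  y <- des$response
  expect_equal(drop(pr$H %*% y), unname(fitted(lm(y ~ 0 + Zint))),
               tolerance = 1e-10)
  # with penalty -> 0 (full df), a noiseless identifiable signal is
  # recovered exactly by ordinary least squares
  fl <- functional_learner(des, 1, df_target = 9)
  prf <- heatlag:::prep_learner(fl, 1:38)
  set.seed(6)
  beta_c <- rnorm(9)
  y_nl <- drop(fl$Z %*% beta_c)
  ols <- drop(solve(crossprod(fl$Z), crossprod(fl$Z, y_nl)))
  expect_equal(drop(prf$A %*% y_nl), ols, tolerance = 1e-6)
  expect_lt(max(abs(prf$H %*% y_nl - y_nl)), 1e-6)
})

test_that("L2 boosting bookkeeping: exact residuals, monotone RSS", {
  toy <- stage2_toy(seed = 7)
  lrn <- default_learners(toy$design)
  fit <- boost(toy$design$response, lrn, m_stop = 40)
  expect_equal(fit$fitted + fit$residuals, toy$design$response)
  preps <- lapply(lrn, heatlag:::prep_learner, rows = 1:38)
  bp <- heatlag:::boost_path(toy$design$response, preps, 0.1, 80)
  expect_true(all(diff(bp$rss) <= 1e-12))
})

test_that("single-learner boosting converges to its projection fix point", {
  toy <- stage2_toy(seed = 8)
  fl <- functional_learner(toy$design, 1, df_target = 8)
  pr <- heatlag:::prep_learner(fl, 1:38)
  y <- toy$design$response
  bp <- heatlag:::boost_path(y, list(pr), 0.1, 4000)
  fitted <- y - mean(y) - bp$residuals
  # limit of repeated shrunken fits: unpenalized projection onto span(Z)
  proj <- drop(fl$Z %*% solve(crossprod(fl$Z), crossprod(fl$Z, y - mean(y))))
  expect_lt(max(abs(fitted - proj)), 1e-6)
})

test_that("pure-noise response stops early and stays near the offset", {
  set.seed(9)
  des <- stage2_toy(seed = 9)$design
  des$response <- rnorm(38, 0.02, 0.01)
  fit <- boost(des$response, default_learners(des), seed = 1)
  expect_lte(fit$m_stop, 15)
  expect_lt(1 - sum(fit$residuals^2) / sum((des$response -
                                              mean(des$response))^2), 0.35)
})

test_that("boosting selects and recovers a planted functional signal", {
  hits <- logical(10); cors <- numeric(10)
  for (r in 1:10) {
    toy <- stage2_toy(seed = 400 + r, r2 = 0.8)
    fit <- boost(toy$design$response, default_learners(toy$design), seed = r)
    hits[r] <- "AMO" %in% fit$selected
    cors[r] <- if (hits[r]) cor(fit$beta_hat$AMO, toy$beta_true) else NA
  }
  expect_gte(mean(hits), 0.9)
  expect_gt(median(cors, na.rm = TRUE), 0.8)
})

test_that("bootstrap bands are reproducible and degenerate at n_boot = 1", {
  toy <- stage2_toy(seed = 10, r2 = 0.6)
  lrn <- default_learners(toy$design)
  fit <- boost(toy$design$response, lrn, seed = 2)
  b1 <- pointwise_ci(fit, toy$design$response, lrn, n_boot = 20, seed = 3)
  b2 <- pointwise_ci(fit, toy$design$response, lrn, n_boot = 20, seed = 3)
  expect_identical(b1, b2)
  one <- pointwise_ci(fit, toy$design$response, lrn, n_boot = 1, seed = 4)
  expect_equal(one$AMO[, "lo"], one$AMO[, "hi"])
})

test_that("boost validates its arguments", {
  toy <- stage2_toy(seed = 11)
  lrn <- default_learners(toy$design)
  expect_error(boost(toy$design$response, lrn, m_max = 0), "m_max")
  expect_error(boost(toy$design$response[1:5], lrn[1:2], rows = 1:5,
                     cv_folds = 10), "fewer than 2")
})
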