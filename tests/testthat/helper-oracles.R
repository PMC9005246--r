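# Independent oracles used across the suite.  These re-derive quantities
# from first principles (recursions, double loops, direct solves) and must
# never call the implementation paths they check.

# Cox-de Boor recursion for a B-spline basis on an augmented knot vector.
# Hand-written, scalar, O(n * k^2); evaluation points must be interior.
bspline_oracle <- function(x, aug, degree) {
  nb <- length(aug) - degree - 1L
  out <- matrix(0, length(x), nb)
  for (q in seq_along(x)) {
    t <- x[q]
    b <- as.numeric(t >= aug[-length(aug)] & t < aug[-1])
    for (k in seq_len(degree)) {
      nb_k <- length(b) - 1L
      bnew <- numeric(nb_k)
      for (i in seq_len(nb_k)) {
        d1 <- aug[i + k] - aug[i]
        d2 <- aug[i + k + 1] - aug[i + 1]
        w1 <- if (d1 > 0) (t - aug[i]) / d1 else 0
        w2 <- if (d2 > 0) (aug[i + k + 1] - t) / d2 else 0
        bnew[i] <- w1 * b[i] + w2 * b[i + 1]
      }
      b <- bnew
    }
    out[q, ] <- b
  }
  out
}

# the augmented knot vector a basis_spec implies (mirrors the documented
# construction so the oracle shares only the knot definition, not the code)
aug_knots <- function(spec) {
  d <- spec$degree
  if (spec$kind == "pspline") {
    dx <- diff(spec$boundary) / (length(spec$knots) + 1L)
    seq(spec$boundary[1] - d * dx, spec$boundary[2] + d * dx, by = dx)
  } else {
    c(rep(spec$boundary[1], d + 1), spec$knots, rep(spec$boundary[2], d + 1))
  }
}

# double-loop cross-basis evaluation with the constant-extrapolation
# season-boundary rule
crossbasis_oracle <- function(tmean, dates, var_spec, lag_spec, max_lag) {
  Blag <- eval_basis(lag_spec, 0:max_lag)
  v <- n_basis(var_spec); p <- ncol(Blag)
  yrs <- strftime(dates, "%Y")
  out <- matrix(0, length(tmean), v * p)
  for (t in seq_along(tmean)) {
    first <- min(which(yrs == yrs[t]))
    for (i in seq_len(v)) for (j in seq_len(p)) {
      s <- 0
      for (l in 0:max_lag) {
        tl <- max(t - l, first)
        s <- s + eval_basis(var_spec, tmean[tl])[1, i] * Blag[l + 1, j]
      }
      out[t, (i - 1) * p + j] <- s
    }
  }
  out
}

# truth-implied annual AF above the true MMT: expected deaths with vs
# without the excess-risk surface (exact forward-simulation limit)
truth_af_mmt <- function(series, truth) {
  mu <- attr(series, "mu"); mu0 <- attr(series, "mu0")
  yrs <- strftime(series$date, "%Y")
  hot <- series$tmean > truth$mmt_true
  tapply(seq_along(mu), yrs,
         function(i) sum((mu[i] - mu0[i])[hot[i]]) / sum(mu[i]))
}

# small synthetic study for fast unit tests
small_study <- function(years = 2001:2012, baseline = 25, seed = 1,
                        truth = synthetic_truth(), gamma = 1.5) {
  simulate_study(years, truth, gamma = gamma, baseline = baseline,
                 seed = seed)
}

# stage-2 toy: response carrying signal from one index only, at a given
# true R-squared
stage2_toy <- function(seed, r2 = 0.3, active = "AMO", years = 1981:2018,
                       rho_active = 0.9) {
  panel <- simulate_indices(years, seed = seed, rho_active = rho_active)
  des <- build_functional_design(data.frame(year = years, af = 0), panel)
  bt <- synthetic_truth()$beta_true(0:16)
  sig <- vapply(seq_along(years), function(i)
    sum(des$quad_weights * bt * des$curves[i, active, ]), numeric(1))
  set.seed(seed + 50000L)
  des$response <- sig + stats::rnorm(length(years),
                                     sd = sqrt(stats::var(sig) * (1 - r2) / r2))
  list(design = des, beta_true = bt, signal = sig)
}
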