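#' Build the stage-2 functional design
#'
#' Stacks, for each study year, the monthly curves of every climate index
#' over the 17-node lag window: lag 0 is May of the AF's year and lag 16 is
#' January of the previous year (lag axis ordered recent to past).  Each
#' index is z-scored over all (year, lag) cells, so functional coefficients
#' are per-SD effects, and trapezoidal quadrature weights on the unit
#' monthly grid discretize the lag integral.
#'
#' @param af Data frame with columns `year` and `af` (one heat definition).
#' @param panel Monthly index panel (`year`, `month`, one column per index)
#'   covering January of the first study year minus one through May of the
#'   last.
#' @param index_names Index columns to use; default all non-date columns.
#' @param n_lags Number of monthly lag nodes (17 spans the 16-month window).
#' @return List of class `"functional_design"`: `response`, `years`,
#'   `curves` (n x J x n_lags array), `index_names`, `quad_weights`,
#'   `standardization`.
#' @export
build_functional_design <- function(af, panel, index_names = NULL,
                                    n_lags = 17L) {
  stopifnot(all(c("year", "af") %in% names(af)))
  if (is.null(index_names))
    index_names <- setdiff(names(panel), c("year", "month"))
  years <- as.integer(af$year)
  key <- paste(panel$year, panel$month)
  curves <- array(NA_real_, c(length(years), length(index_names), n_lags),
                  dimnames = list(years, index_names, NULL))
  for (k in seq_along(years)) {
    mo <- 5L - 0:(n_lags - 1L)                  # calendar month per lag
    yr <- years[k] + ifelse(mo >= 1L, 0L, -1L)
    mo <- ifelse(mo >= 1L, mo, mo + 12L)
    rows <- match(paste(yr, mo), key)
    for (j in seq_along(index_names)) {
      v <- panel[[index_names[j]]][rows]
      if (anyNA(v)) {
        miss <- which(is.na(v))[1]
        stop("missing month for index ", index_names[j], ": ",
             yr[miss], "-", mo[miss])
      }
      curves[k, j, ] <- v
    }
  }
  std <- data.frame(index = index_names,
                    mean = apply(curves, 2, mean),
                    sd = apply(curves, 2, stats::sd))
  for (j in seq_along(index_names))
    curves[, j, ] <- (curves[, j, ] - std$mean[j]) / std$sd[j]
  w <- c(0.5, rep(1, n_lags - 2L), 0.5)
  structure(list(response = af$af, years = years, curves = curves,
                 index_names = index_names, quad_weights = w,
                 standardization = std),
            class = "functional_design")
}

# lambda such that tr(Z (Z'Z + lambda P)^-1 Z') = df_target
solve_ridge_df <- function(ZtZ, P, df_target) {
  edf <- function(lam) sum(diag(solve(ZtZ + lam * P, ZtZ)))
  if (all(P == 0)) {
    d0 <- qr(ZtZ)$rank
    if (d0 < df_target - 0.05)
      stop("df_target exceeds the learner's unpenalized df")
    return(0)
  }
  scale <- mean(diag(ZtZ)) / mean(diag(P))
  lo <- 1e-10 * scale
  d0 <- edf(lo)
  if (d0 < df_target - 0.05)
    stop("df_target exceeds the learner's unpenalized df")
  if (d0 <= df_target) return(lo)          # df-saturated: no shrinkage
  hi <- scale
  while (edf(hi) > df_target) hi <- hi * 10
  stats::uniroot(function(ll) edf(exp(ll)) - df_target,
                 c(log(lo), log(hi)), tol = 1e-10)$root |> exp()
}

new_learner <- function(name, type, Z, P, df_target, meta = list()) {
  structure(list(name = name, type = type, Z = Z, P = P,
                 df_target = df_target, meta = meta),
            class = "base_learner")
}

#' Functional base learner for one index curve
#'
#' Expands the functional coefficient `beta_j(l)` in a cubic B-spline basis
#' on the lag grid so the integral term reduces to a linear term: row `i` of
#' the learner design is `sum_l w_l x_ijl B_k(l)`.  A second-order
#' difference penalty on the spline coefficients, with its ridge scale
#' solved by bisection so the learner's hat-matrix trace equals
#' `df_target`, makes all base learners equally flexible — a requirement
#' for unbiased selection in component-wise boosting.
#'
#' @param design A [build_functional_design()].
#' @param j Index number or name.
#' @param df_target Common effective degrees of freedom.
#' @param n_knots Interior knots of the coefficient spline.
#' @param penalty_order Difference-penalty order.
#' @return A base learner (used by [boost()]).
#' @export
functional_learner <- function(design, j, df_target = 4, n_knots = 5L,
                               penalty_order = 2L) {
  if (is.character(j)) j <- match(j, design$index_names)
  n_lags <- dim(design$curves)[3]
  grid <- 0:(n_lags - 1L)
  spec <- basis_spec("pspline", degree = 3L,
                     knots = seq(0, n_lags - 1L,
                                 length.out = n_knots + 2L)[-c(1, n_knots + 2L)],
                     boundary = c(0, n_lags - 1L), intercept = TRUE)
  B <- bspline_basis(grid, spec)                        # n_lags x K
  X <- design$curves[, j, ]                             # n x n_lags
  Z <- (X * matrix(design$quad_weights, nrow(X), n_lags, byrow = TRUE)) %*% B
  P <- pspline_penalty(ncol(B), penalty_order)
  new_learner(design$index_names[j], "functional", Z, P, df_target,
              meta = list(lag_grid = grid, B_grid = unclass(B)))
}

#' Smooth-year base learner (P-spline)
#'
#' Dense cubic B-spline of the year (20 interior knots by default) with a
#' second-order difference penalty, capturing the smooth long-term
#' component of the annual AF series.  The penalty null space contains
#' linear trends, so those are never shrunk away.
#'
#' @param design A [build_functional_design()] (supplies the years).
#' @param df_target Common effective degrees of freedom.
#' @param n_knots Interior knots; reduced with a warning when there are too
#'   few distinct years to support the full basis.
#' @return A base learner.
#' @export
year_learner <- function(design, df_target = 4, n_knots = 20L) {
  years <- design$years
  nd <- length(unique(years))
  if (nd < n_knots + 2L) {
    n_knots <- max(1L, nd - 2L)
    warning("too few distinct years; reducing year-spline knots to ", n_knots)
  }
  rng <- range(years)
  spec <- basis_spec("pspline", degree = 3L,
                     knots = seq(rng[1], rng[2],
                                 length.out = n_knots + 2L)[-c(1, n_knots + 2L)],
                     boundary = rng, intercept = TRUE)
  B <- bspline_basis(years, spec)
  new_learner("year", "year", unclass(B), pspline_penalty(ncol(B), 2L),
              df_target, meta = list(spec = spec))
}

#' Scalar linear base learner
#'
#' A single centered linear term (e.g. mean summer temperature for the
#' sensitivity model).  Unpenalized; one degree of freedom.
#'
#' @param x Scalar covariate per year.
#' @param name Learner label.
#' @return A base learner.
#' @export
scalar_learner <- function(x, name = "scalar") {
  Z <- matrix(x - mean(x), ncol = 1)
  new_learner(name, "scalar", Z, matrix(0, 1, 1), 1, meta = list())
}

#' All default stage-2 learners
#' @param design A [build_functional_design()].
#' @param df_target Common effective df of every learner.
#' @param n_knots Interior knots of the functional coefficient splines.
#' @param year_knots Interior knots of the year P-spline.
#' @return List of base learners (one per index plus the year smooth).
#' @export
default_learners <- function(design, df_target = 4, n_knots = 5L,
                             year_knots = 20L) {
  c(lapply(seq_along(design$index_names), function(j)
      functional_learner(design, j, df_target, n_knots)),
    list(year_learner(design, df_target, year_knots)))
}

# precompute solver/hat matrices for a learner restricted to 'rows'
prep_learner <- function(learner, rows) {
  Z <- unname(learner$Z[rows, , drop = FALSE])
  lam <- solve_ridge_df(crossprod(Z), learner$P, learner$df_target)
  A <- solve(crossprod(Z) + lam * learner$P, t(Z))      # K x n
  list(Z = Z, A = A, H = Z %*% A, lambda = lam)
}

# core component-wise L2 boosting loop; returns coefficient list, selection
# path, training RSS path and (optionally) per-iteration test predictions
boost_path <- function(y, preps, nu, m_max, Ztest = NULL) {
  offset <- mean(y)
  r <- y - offset
  J <- length(preps)
  coefs <- lapply(preps, function(p) numeric(ncol(p$Z)))
  path <- integer(m_max)
  rss <- numeric(m_max + 1L); rss[1] <- sum(r^2)
  test_pred <- NULL
  if (!is.null(Ztest)) {
    test_pred <- matrix(offset, nrow(Ztest[[1]]), m_max + 1L)
  }
  for (m in seq_len(m_max)) {
    rss_j <- vapply(preps, function(p) sum((r - p$H %*% r)^2), numeric(1))
    j <- which.min(rss_j)
    inc <- nu * drop(preps[[j]]$A %*% r)
    coefs[[j]] <- coefs[[j]] + inc
    r <- r - nu * drop(preps[[j]]$H %*% r)
    path[m] <- j
    rss[m + 1L] <- sum(r^2)
    if (!is.null(Ztest))
      test_pred[, m + 1L] <- test_pred[, m] + drop(Ztest[[j]] %*% inc)
  }
  list(offset = offset, coefs = coefs, path = path, rss = rss,
       residuals = r, test_pred = test_pred)
}

#' Component-wise gradient boosting for the functional linear model
#'
#' Iteratively fits every base learner to the current residuals, adds
#' `nu` times the best one (lowest residual sum of squares), and stops at
#' the iteration minimizing the 10-fold cross-validated squared prediction
#' error (iteration 0 is the offset-only model).  Because a single learner
#' is updated per iteration, only the most predictive variables ever enter
#' the model, giving implicit variable selection.
#'
#' @param y Response vector (annual AFs).
#' @param learners List of base learners sharing a common `df_target`.
#' @param nu Step length.
#' @param m_max Maximum number of iterations.
#' @param cv_folds Folds for the stopping cross-validation.
#' @param seed Seed for the fold assignment.
#' @param rows Optional row subset to fit on (learner matrices keep full
#'   rows so held-out rows can be predicted).
#' @param m_stop Fix the stopping iteration and skip the CV (used by the
#'   bootstrap bands and by callers that already chose it).
#' @return Object of class `"boost_fit"`: `offset`, `coefs` (per learner),
#'   `selected_path`, `m_stop`, `cv_curve`, `fitted`, `residuals`,
#'   `beta_hat` (functional coefficient curves on the lag grid), `s_hat`
#'   (smooth year values), `selected` (names of learners ever selected).
#' @export
boost <- function(y, learners, nu = 0.1, m_max = 200L, cv_folds = 10L,
                  seed = 1L, rows = NULL, m_stop = NULL) {
  if (m_max < 1) stop("'m_max' must be >= 1")
  if (is.null(rows)) rows <- seq_along(y)
  yr <- y[rows]
  n <- length(yr)
  cv_curve <- NULL
  if (is.null(m_stop)) {
    set.seed(seed)
    fold <- sample(rep(seq_len(cv_folds), length.out = n))
    if (min(tabulate(fold, cv_folds)) < 2)
      stop("a CV fold has fewer than 2 observations; reduce cv_folds")
    sse <- matrix(0, cv_folds, m_max + 1L)
    for (f in seq_len(cv_folds)) {
      tr <- rows[fold != f]; te <- rows[fold == f]
      preps <- lapply(learners, prep_learner, rows = tr)
      Ztest <- lapply(learners, function(l) l$Z[te, , drop = FALSE])
      bp <- boost_path(y[tr], preps, nu, m_max, Ztest = Ztest)
      sse[f, ] <- colSums((y[te] - bp$test_pred)^2)
    }
    cv_curve <- colSums(sse) / n
    m_stop <- which.min(cv_curve) - 1L
  }
  preps <- lapply(learners, prep_learner, rows = rows)
  bp <- boost_path(yr, preps, nu, max(m_stop, 1L), Ztest = NULL)
  if (m_stop == 0L) {
    bp$coefs <- lapply(bp$coefs, function(ci) ci * 0)
    bp$path <- integer(0)
    bp$residuals <- yr - bp$offset
  } else {
    bp$path <- bp$path[seq_len(m_stop)]
  }
  fitted <- bp$offset + Reduce(`+`, Map(function(l, ci)
    drop(unname(l$Z[rows, , drop = FALSE]) %*% ci), learners, bp$coefs))
  nm <- vapply(learners, `[[`, character(1), "name")
  beta_hat <- list()
  s_hat <- NULL
  for (j in seq_along(learners)) {
    if (learners[[j]]$type == "functional")
      beta_hat[[nm[j]]] <- drop(learners[[j]]$meta$B_grid %*% bp$coefs[[j]])
    if (learners[[j]]$type == "year")
      s_hat <- drop(learners[[j]]$Z[rows, , drop = FALSE] %*% bp$coefs[[j]])
  }
  structure(
    list(offset = bp$offset, coefs = stats::setNames(bp$coefs, nm),
         selected_path = nm[bp$path], m_stop = m_stop, cv_curve = cv_curve,
         nu = nu, rows = rows, fitted = fitted, residuals = yr - fitted,
         beta_hat = beta_hat, s_hat = s_hat,
         selected = unique(nm[bp$path]), learner_names = nm),
    class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  cat("Component-wise L2 boosting: m_stop = ", x$m_stop,
      ", nu = ", x$nu, "\n", sep = "")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none - offset only)", "\n")
  invisible(x)
}

#' Predict from a boosting fit
#' @param object A [boost()] fit.
#' @param learners The learner list used to fit.
#' @param rows Row indices (into the full design) to predict.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.boost_fit <- function(object, learners, rows, ...) {
  object$offset + Reduce(`+`, Map(function(l, ci)
    drop(unname(l$Z[rows, , drop = FALSE]) %*% ci), learners, object$coefs))
}

#' Bootstrap pointwise bands for the functional coefficients
#'
#' Nonparametric bootstrap over years: years are resampled with
#' replacement, the boosting is refit with the stopping iteration fixed at
#' the original `m_stop`, and pointwise 2.5/97.5 percentiles of each
#' `beta_hat_j(l)` are taken per lag.
#'
#' @param fit A [boost()] fit.
#' @param y Response vector.
#' @param learners Learner list used for `fit`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Named list (functional learners only) of matrices with columns
#'   `lo`, `hi` and one row per lag.
#' @export
pointwise_ci <- function(fit, y, learners, n_boot = 200L, seed = 1L) {
  set.seed(seed)
  n <- length(y)
  fl <- which(vapply(learners, `[[`, character(1), "type") == "functional")
  curves <- lapply(fl, function(j)
    matrix(NA_real_, n_boot, nrow(learners[[j]]$meta$B_grid)))
  names(curves) <- vapply(learners[fl], `[[`, character(1), "name")
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n, replace = TRUE)
    bf <- boost(y, learners, nu = fit$nu, rows = rows, m_stop = fit$m_stop)
    for (k in seq_along(fl))
      curves[[k]][b, ] <- bf$beta_hat[[names(curves)[k]]]
  }
  lapply(curves, function(M) {
    q <- apply(M, 2, stats::quantile, probs = c(0.025, 0.975))
    cbind(lo = q[1, ], hi = q[2, ])
  })
}
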