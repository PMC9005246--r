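#' Default temperature and lag basis specifications
#'
#' The temperature dimension uses a quadratic B-spline with interior knots
#' at the 50th and 90th percentiles of the pooled May-September temperature
#' distribution, boundary knots at the observed range, and no intercept (the
#' model intercept lives in the regression).  The lag dimension uses a
#' natural cubic spline with two interior knots equally spaced on the log
#' scale over lags `0..max_lag` and an intercept.
#'
#' @param tmean Pooled daily mean temperatures (degC).
#' @param knot_percentiles Percentiles for the temperature knots.
#' @param max_lag Maximum lag (days).
#' @param n_knots Number of interior log-scale lag knots.
#' @return A [basis_spec()].
#' @export
default_var_spec <- function(tmean, knot_percentiles = c(0.5, 0.9)) {
  basis_spec("bspline", degree = 2L,
             knots = unname(stats::quantile(tmean, knot_percentiles)),
             boundary = range(tmean), intercept = FALSE)
}

#' @rdname default_var_spec
#' @export
default_lag_spec <- function(max_lag = 10L, n_knots = 2L) {
  basis_spec("natural-cubic", knots = log_lag_knots(max_lag, n_knots),
             boundary = c(0, max_lag), intercept = TRUE)
}

#' Build the temperature-lag cross-basis
#'
#' Constructs the design-matrix block of a distributed lag nonlinear model:
#' row `t`, column `(i, j)` equals
#' `sum over l of B_var,i(tmean[t - l]) * B_lag,j(l)` for lags `0..max_lag`,
#' in var-major column order (`(i - 1) * p + j`).  Exposure histories never
#' cross the September-to-May gap: within each season the first `max_lag`
#' days use constant extrapolation, i.e. lagged temperatures before the
#' season's first day are taken as its first observed value.
#'
#' @param tmean Daily mean temperatures, ordered by date.
#' @param dates Matching `Date` vector; the calendar year defines seasons.
#' @param var_spec,lag_spec [basis_spec()]s for the two dimensions
#'   (defaults: [default_var_spec()], [default_lag_spec()]).
#' @param max_lag Maximum lag in days.
#' @return A numeric matrix of class `"crossbasis"` with `v * p` columns and
#'   attributes `var_spec`, `lag_spec`, `max_lag`, `lag_basis` (the lag
#'   basis at integer lags) and `Clag` (its column sums, used for overall
#'   cumulative predictions).
#' @export
build_crossbasis <- function(tmean, dates, var_spec = NULL, lag_spec = NULL,
                             max_lag = 10L) {
  stopifnot(length(tmean) == length(dates), !is.unsorted(dates))
  if (is.null(var_spec)) var_spec <- default_var_spec(tmean)
  if (is.null(lag_spec)) lag_spec <- default_lag_spec(max_lag)
  Blag <- eval_basis(lag_spec, 0:max_lag)
  p <- ncol(Blag)
  v <- n_basis(var_spec)
  seasons <- split(seq_along(tmean), as.integer(strftime(dates, "%Y")))
  n <- length(tmean)
  CB <- matrix(0, n, v * p)
  for (idx in seasons) {
    if (length(idx) < max_lag + 1)
      stop("season shorter than max_lag + 1 days")
    x <- tmean[idx]
    for (l in 0:max_lag) {
      xl <- c(rep(x[1], l), x[seq_len(length(x) - l)])
      Bv <- eval_basis(var_spec, xl)
      CB[idx, ] <- CB[idx, ] +
        Bv[, rep(seq_len(v), each = p), drop = FALSE] *
        matrix(Blag[l + 1L, ], length(idx), v * p, byrow = TRUE)
    }
  }
  colnames(CB) <- paste0("v", rep(seq_len(v), each = p),
                         ".l", rep(seq_len(p), v))
  structure(CB, var_spec = var_spec, lag_spec = lag_spec,
            max_lag = as.integer(max_lag), lag_basis = Blag,
            Clag = colSums(Blag), class = c("crossbasis", class(CB)))
}

# kronecker-per-row expansion matching the var-major cross-basis layout
kron_rows <- function(Bvar, Clag) {
  v <- ncol(Bvar); p <- length(Clag)
  Bvar[, rep(seq_len(v), each = p), drop = FALSE] *
    matrix(rep(Clag, v), nrow(Bvar), v * p, byrow = TRUE)
}
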