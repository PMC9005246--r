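#' Describe a spline basis
#'
#' Light-weight specification object consumed by [bspline_basis()],
#' [natural_cubic_basis()] and the cross-basis constructor.  A spec fixes the
#' basis family, its interior knots and boundary, so that the same basis can
#' be re-evaluated at new abscissae (e.g. a temperature grid for prediction).
#'
#' @param kind One of `"bspline"`, `"natural-cubic"`, `"pspline"`.  A
#'   `"pspline"` is a B-spline that additionally carries a difference-penalty
#'   order.
#' @param degree Polynomial degree (B-splines only; natural cubic splines are
#'   always cubic).
#' @param knots Ordered vector of interior knots, strictly inside `boundary`.
#' @param boundary Length-2 numeric, the boundary knots `(lo, hi)`.
#' @param intercept Keep the full basis (`TRUE`) or drop the first column so
#'   the basis is identifiable next to a model intercept (`FALSE`).
#' @param penalty_order Order of the difference penalty attached to a
#'   `"pspline"` basis (ignored otherwise).
#'
#' @return An object of class `"basis_spec"`.
#' @export
basis_spec <- function(kind = c("bspline", "natural-cubic", "pspline"),
                       degree = 3L, knots = numeric(0), boundary,
                       intercept = FALSE, penalty_order = 2L) {
  kind <- match.arg(kind)
  knots <- as.numeric(knots)
  if (is.unsorted(knots, strictly = TRUE) && length(knots) > 1)
    stop("interior knots must be strictly increasing")
  if (missing(boundary) || length(boundary) != 2 || boundary[1] >= boundary[2])
    stop("'boundary' must be (lo, hi) with lo < hi")
  if (length(knots) && (min(knots) <= boundary[1] || max(knots) >= boundary[2]))
    stop("interior knots must lie strictly inside the boundary")
  if (kind != "natural-cubic" && degree < 1)
    stop("'degree' must be >= 1 for a B-spline basis")
  structure(
    list(kind = kind, degree = if (kind == "natural-cubic") 3L else as.integer(degree),
         knots = knots, boundary = as.numeric(boundary),
         intercept = isTRUE(intercept),
         penalty_order = as.integer(penalty_order)),
    class = "basis_spec")
}

#' Number of columns a basis spec produces
#' @param spec A [basis_spec()].
#' @return Integer column count.
#' @export
n_basis <- function(spec) {
  k <- length(spec$knots)
  switch(spec$kind,
         "bspline" = ,
         "pspline" = k + spec$degree + 1L - !spec$intercept,
         "natural-cubic" = k + 1L + spec$intercept)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate a B-spline basis
#'
#' Evaluates the B-spline basis defined by `spec` at `x` via the Cox-de Boor
#' recursion (through [splines::splineDesign()]).  Values outside the
#' boundary are clamped to the boundary before evaluation.  Inside the
#' boundary the full basis is a partition of unity: each row sums to 1.
#'
#' A `"bspline"` basis uses repeated boundary knots (the usual regression
#' spline, allowing arbitrary interior knots such as temperature
#' percentiles).  A `"pspline"` basis requires equally spaced interior
#' knots and extends the equidistant grid `degree` knots beyond each
#' boundary, so that the difference penalty's null space contains exactly
#' the polynomials of degree below the penalty order (a linear trend is
#' never shrunk by a second-order penalty).
#'
#' @param x Numeric vector of evaluation points.
#' @param spec A [basis_spec()] with `kind` `"bspline"` or `"pspline"`.
#' @return A numeric matrix with `length(x)` rows; attributes `spec` and,
#'   for a P-spline, the difference `penalty` matrix.
#' @export
bspline_basis <- function(x, spec) {
  if (!inherits(spec, "basis_spec") || !spec$kind %in% c("bspline", "pspline"))
    stop("'spec' must be a bspline/pspline basis_spec")
  if (anyDuplicated(spec$knots)) stop("duplicate interior knots")
  d <- spec$degree
  lo <- spec$boundary[1]; hi <- spec$boundary[2]
  if (spec$kind == "pspline") {
    dx <- (hi - lo) / (length(spec$knots) + 1L)
    if (length(spec$knots) &&
        max(abs(spec$knots - (lo + dx * seq_along(spec$knots)))) > 1e-8 * dx)
      stop("pspline requires equally spaced interior knots")
    aug <- seq(lo - d * dx, hi + d * dx, by = dx)
  } else {
    aug <- c(rep(lo, d + 1), spec$knots, rep(hi, d + 1))
  }
  B <- splines::splineDesign(aug, clamp(x, lo, hi), ord = d + 1L)
  if (!spec$intercept) B <- B[, -1L, drop = FALSE]
  pen <- NULL
  if (spec$kind == "pspline")
    pen <- pspline_penalty(ncol(B), spec$penalty_order)
  structure(B, spec = spec, penalty = pen)
}

#' Evaluate a natural cubic spline basis
#'
#' Cubic spline basis constrained to be linear beyond the boundary knots
#' (second derivative zero at and outside the boundaries), as used for the
#' lag dimension of the cross-basis and for the trend/seasonality controls.
#' Built on [splines::ns()] with fixed knots so the basis is reproducible at
#' new evaluation points.
#'
#' @inheritParams bspline_basis
#' @param spec A [basis_spec()] with `kind = "natural-cubic"`.
#' @return Numeric matrix, `length(spec$knots) + 1 + intercept` columns.
#' @export
natural_cubic_basis <- function(x, spec) {
  if (!inherits(spec, "basis_spec") || spec$kind != "natural-cubic")
    stop("'spec' must be a natural-cubic basis_spec")
  if (anyDuplicated(spec$knots)) stop("duplicate interior knots")
  B <- splines::ns(x, knots = spec$knots, Boundary.knots = spec$boundary,
                   intercept = spec$intercept)
  structure(unclass(B)[, , drop = FALSE], spec = spec, penalty = NULL)
}

#' Evaluate any basis spec
#' @param spec A [basis_spec()].
#' @param x Evaluation points.
#' @return Basis matrix (see the kind-specific constructors).
#' @export
eval_basis <- function(spec, x) {
  switch(spec$kind,
         "bspline" = ,
         "pspline" = bspline_basis(x, spec),
         "natural-cubic" = natural_cubic_basis(x, spec))
}

#' Interior knots equally spaced on the log-lag scale
#'
#' Places `n_knots` interior knots at equal log spacing over `(0, max_lag]`:
#' `knot_k = exp(k * log(max_lag) / (n_knots + 1))`.  This is the standard
#' placement for the lag dimension of distributed lag models, concentrating
#' flexibility at short lags where effects change fastest; the basis itself
#' is still evaluated on the original lag scale `0..max_lag`.
#'
#' @param max_lag Maximum lag in days (>= 1).
#' @param n_knots Number of interior knots (>= 1).
#' @return Increasing numeric vector of knots inside `(0, max_lag)`.
#' @export
log_lag_knots <- function(max_lag, n_knots) {
  stopifnot(max_lag >= 1, n_knots >= 1)
  exp(seq_len(n_knots) * log(max_lag) / (n_knots + 1))
}

#' Difference penalty matrix for P-splines
#'
#' Returns `t(D) %*% D` where `D` is the `order`-th difference operator on
#' `n_basis` coefficients.  The quadratic form `b' P b` is the sum of squared
#' `order`-th differences of `b`; its null space is the polynomials of degree
#' `< order` in the coefficient index, so the matrix has rank
#' `n_basis - order`.
#'
#' @param n_basis Number of basis coefficients (> `order`).
#' @param order Difference order (default 2).
#' @return `n_basis` x `n_basis` positive semidefinite matrix.
#' @export
pspline_penalty <- function(n_basis, order = 2L) {
  stopifnot(n_basis > order, order >= 1)
  D <- diff(diag(n_basis), differences = order)
  crossprod(D)
}
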