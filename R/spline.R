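#' Natural cubic interpolating spline on a fixed knot grid
#'
#' The age-dependent acceleration bias \eqn{b(t)} and the (unconstrained-scale)
#' process-noise level are parameterized as natural cubic interpolating
#' splines through five control points placed at equally spaced ages. The
#' spline passes exactly through each `(knot, value)` pair, is C2 inside the
#' knot range, and is clamped to the boundary control value outside it so
#' that extreme ages never trigger cubic extrapolation.
#'
#' @param values numeric vector of control values, one per knot.
#' @param knots numeric vector of knot ages in years; default five knots
#'   equally spaced over 18--100 years.
#' @return an object of class `nc_spline`.
#' @examples
#' sp <- nc_spline(c(0, -1, -2, -5, -9))
#' eval_spline(sp, 60)
#' @export
nc_spline <- function(values, knots = default_knots()) {
  stopifnot(length(values) == length(knots), length(knots) >= 3)
  if (!all(is.finite(knots)) || is.unsorted(knots, strictly = TRUE))
    stop("knots must be finite and strictly increasing")
  structure(list(knots = as.numeric(knots), values = as.numeric(values)),
            class = "nc_spline")
}

#' Default spline knots: five ages equally spaced over 18 to 100 years
#' @return numeric vector of length 5.
#' @export
default_knots <- function() seq(18, 100, length.out = 5)

#' Evaluate a natural cubic spline
#'
#' @param spline an [nc_spline()] object.
#' @param t ages in years; values outside the knot range are clamped to the
#'   nearest boundary before evaluation (constant extrapolation).
#' @return numeric vector of spline values at `t`.
#' @export
eval_spline <- function(spline, t) {
  stopifnot(inherits(spline, "nc_spline"))
  if (!all(is.finite(t))) stop("spline evaluation requires finite ages")
  if (all(!is.finite(spline$values))) {
    # degenerate all -Inf control values encode an identically -Inf level
    return(rep(spline$values[1], length(t)))
  }
  tc <- pmin(pmax(t, spline$knots[1]), spline$knots[length(spline$knots)])
  f <- stats::splinefun(spline$knots, spline$values, method = "natural")
  f(tc)
}

#' Linear basis matrix of the natural cubic spline
#'
#' Natural cubic interpolation is linear in the control values; this returns
#' the matrix `W` with `W %*% values` equal to the spline evaluated at `t`
#' (after boundary clamping). Used to make the fit objective linear in the
#' spline coordinates.
#'
#' @param knots knot ages.
#' @param t evaluation ages.
#' @return a `length(t)` by `length(knots)` matrix.
#' @keywords internal
spline_basis <- function(knots, t) {
  n <- length(knots)
  W <- matrix(0, length(t), n)
  tc <- pmin(pmax(t, knots[1]), knots[n])
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    W[, j] <- stats::splinefun(knots, e, method = "natural")(tc)
  }
  W
}

#' Softplus link and its inverse
#'
#' `softplus(x) = log(1 + exp(x))`, the positivity link used for the
#' feedback coefficients, the process-noise SD `sigma_q(t)` and the site
#' noise SDs. `softplus_inv` maps a positive value back to the
#' unconstrained scale, e.g. to express noise-SD control values as spline
#' coordinates.
#'
#' @param x unconstrained values.
#' @param y positive values.
#' @return numeric vector.
#' @export
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' @rdname softplus
#' @export
softplus_inv <- function(y) {
  stopifnot(all(y >= 0))
  ifelse(y > 30, y, log(expm1(pmax(y, 1e-300))))
}
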