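# Dimensionless field of the uniform square sheet source.
#
# In units of the square side a, the shape function is
#   F(x, y, z) = int_{-1/2}^{1/2} int_{-1/2}^{1/2} dxi deta /
#                sqrt((x - xi)^2 + (y - eta)^2 + z^2)
# i.e. the Newtonian potential of a uniform unit sheet over [-1/2,1/2]^2,
# evaluated through the two-medium interface kernel. Multiply by t1 for
# degrees C. Two independent routes are provided: adaptive 2-D quadrature
# (any z) and the analytic closed form on the surface z = 0.

degenerate_point_error <- function(msg) {
  stop(errorCondition(
    msg, class = c("thermofield_degenerate_point_error", "error", "condition")
  ))
}

convergence_error <- function(msg, estimate) {
  stop(errorCondition(
    msg, estimate = estimate,
    class = c("thermofield_convergence_error", "error", "condition")
  ))
}

# split an integration range at interior break points
.split_at <- function(lo, hi, breaks) {
  b <- breaks[breaks > lo & breaks < hi]
  sort(unique(c(lo, b, hi)))
}

.integrate_piecewise <- function(f, lo, hi, breaks, rel_tol) {
  pts <- .split_at(lo, hi, breaks)
  total <- 0
  err <- 0
  for (k in seq_len(length(pts) - 1L)) {
    res <- stats::integrate(
      f, pts[k], pts[k + 1L],
      rel.tol = rel_tol, abs.tol = 0,
      subdivisions = 400L, stop.on.error = FALSE
    )
    if (!res$message %in% c("OK", "roundoff error was detected")) {
      convergence_error(
        sprintf("quadrature failed on [%g, %g]: %s", pts[k], pts[k + 1L],
                res$message),
        estimate = res$abs.error
      )
    }
    total <- total + res$value
    err <- err + res$abs.error
  }
  list(value = total, abs_error = err)
}

#' Square-sheet shape function by adaptive quadrature
#'
#' Evaluates the dimensionless square-source field anywhere in space by
#' nested adaptive quadrature of the sheet-potential double integral. The
#' integrand's 1/R singularity for surface points on the sheet is integrable;
#' it is handled by splitting both integration ranges at the field point, so
#' the singular line falls on panel endpoints that the Gauss-Kronrod rule
#' never samples.
#'
#' @param xa,ya,za Field point in units of the square side a (`za > 0` air,
#'   `za < 0` tissue, `za = 0` the interface). Scalars.
#' @param rel_tol Relative tolerance of the outer quadrature. The inner
#'   integral is solved 100x tighter.
#' @return The positive dimensionless field value; multiply by `t1` to get
#'   degrees C. Symmetric in `za <-> -za`.
#' @seealso [square_shape_surface()] for the exact surface closed form.
#' @examples
#' square_shape_quadrature(0, 0, 0)   # 4*log(1 + sqrt(2))
#' @export
square_shape_quadrature <- function(xa, ya, za = 0, rel_tol = 1e-9) {
  stopifnot(
    is.finite(xa), is.finite(ya), is.finite(za),
    length(xa) == 1L, length(ya) == 1L, length(za) == 1L
  )
  za2 <- za^2
  inner <- function(eta_vec) {
    vapply(eta_vec, function(eta) {
      c2 <- (ya - eta)^2 + za2
      f <- function(xi) 1 / sqrt((xa - xi)^2 + c2)
      .integrate_piecewise(f, -0.5, 0.5, breaks = xa,
                           rel_tol = rel_tol / 100)$value
    }, numeric(1L))
  }
  res <- .integrate_piecewise(inner, -0.5, 0.5, breaks = ya,
                              rel_tol = rel_tol)
  if (!is.finite(res$value) || res$value <= 0) {
    convergence_error("quadrature produced a non-finite or non-positive value",
                      estimate = res$abs_error)
  }
  res$value
}

# antiderivative of the sheet potential: d2H/dXdY = 1/sqrt(X^2 + Y^2).
# Terms with a zero coefficient are forced to 0 so that edge points
# (where the log argument vanishes together with its prefactor) stay
# finite; log(Y + r) with Y < 0 is rewritten via Y + r = X^2/(r - Y) to
# avoid catastrophic cancellation near the corners.
.sheet_H <- function(X, Y) {
  r <- sqrt(X^2 + Y^2)
  safe_log <- function(A, B) {
    # log(A + r) with coefficient B in front; A, B are the two coordinates
    ifelse(A >= 0, log(A + r), 2 * log(abs(B)) - log(r - A))
  }
  tx <- ifelse(X == 0, 0, X * safe_log(Y, X))
  ty <- ifelse(Y == 0, 0, Y * safe_log(X, Y))
  tx + ty
}

#' Square-sheet shape function on the surface (closed form)
#'
#' Exact integration of the sheet potential at `z = 0` in elementary
#' functions: the classical uniform-rectangle potential, a four-corner
#' difference of `H(X, Y) = X log(Y + R) + Y log(X + R)` with R the corner
#' distance. Equals [square_shape_quadrature()] at `za = 0` to the
#' quadrature tolerance everywhere except the four sheet corners, where the
#' log arguments degenerate.
#'
#' @param xa,ya Surface field point in units of a. Vectorized.
#' @return Dimensionless field value(s); strictly positive, maximal at the
#'   origin where it equals `4 log(1 + sqrt(2))`.
#' @examples
#' square_shape_surface(0, 0)       # 3.525494
#' square_shape_surface(0.3, 0.1) == square_shape_surface(0.1, 0.3)
#' @export
square_shape_surface <- function(xa, ya) {
  n <- max(length(xa), length(ya))
  xa <- rep_len(as.numeric(xa), n)
  ya <- rep_len(as.numeric(ya), n)
  if (!all(is.finite(xa)) || !all(is.finite(ya))) {
    validation_error("xa/ya", "must be finite")
  }
  if (any(abs(xa) == 0.5 & abs(ya) == 0.5)) {
    degenerate_point_error(paste(
      "evaluation exactly at a sheet corner (+/-1/2, +/-1/2) is degenerate;",
      "offset the point by ~1e-12"
    ))
  }
  .sheet_H(0.5 - xa, 0.5 - ya) - .sheet_H(-0.5 - xa, 0.5 - ya) -
    .sheet_H(0.5 - xa, -0.5 - ya) + .sheet_H(-0.5 - xa, -0.5 - ya)
}
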