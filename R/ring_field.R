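# Dimensionless field of the O-ring line source.
#
# With u = 2r/a and w = 2(z - z0)/a, the shape function is the angular
# integral
#   G(r, z) = int_0^pi dphi / sqrt(1 + u^2 - 2 u cos(phi) + w^2)
# On the surface plane of the ring (w = 0) it reduces exactly to
#   G = (2 / (1 + u)) * K(2 sqrt(u) / (1 + u))
# with K the complete elliptic integral of the first kind in the modulus
# convention K(k) = int_0^{pi/2} dtheta / sqrt(1 - k^2 sin^2 theta).
# The field diverges logarithmically on the wire (u = 1, w = 0).

singular_point_error <- function(msg) {
  stop(errorCondition(
    msg, class = c("thermofield_singular_point_error", "error", "condition")
  ))
}

out_of_validity_error <- function(msg) {
  stop(errorCondition(
    msg, class = c("thermofield_out_of_validity_error", "error", "condition")
  ))
}

#' Complete elliptic integral of the first kind
#'
#' `K(k) = int_0^{pi/2} dtheta / sqrt(1 - k^2 sin^2 theta)`, computed by the
#' arithmetic-geometric mean: `K(k) = pi / (2 AGM(1, sqrt(1 - k^2)))`.
#' Converges quadratically; machine precision in a handful of iterations.
#'
#' @param k Modulus, `0 <= k < 1`. Vectorized.
#' @return K(k).
#' @examples
#' elliptic_K(0)   # pi/2
#' @export
elliptic_K <- function(k) {
  k <- as.numeric(k)
  if (any(!is.finite(k) | k < 0 | k >= 1)) {
    validation_error("k", "modulus must satisfy 0 <= k < 1")
  }
  a <- rep_len(1, length(k))
  b <- sqrt(1 - k^2)
  for (i in 1:60) {
    if (all(abs(a - b) <= 4 * .Machine$double.eps * a)) break
    an <- (a + b) / 2
    b <- sqrt(a * b)
    a <- an
  }
  pi / (2 * a)
}

#' Ring shape function by angular quadrature
#'
#' Evaluates the dimensionless O-ring field anywhere (any radial distance
#' `ra = r/a`, any heights) by adaptive quadrature of the angular integral.
#' Radially symmetric by construction; depends on heights only through
#' `|za - z0a|`. The point `ra = 1/2`, `za = z0a` lies on the ideal wire and
#' is a true logarithmic singularity: a guard band of 1e-6 around it raises
#' a singular-point error.
#'
#' @param ra Radial coordinate `sqrt(x^2 + y^2)/a`, >= 0. Vectorized.
#' @param za Height in units of a.
#' @param z0a Ring standoff `z0/a` (>= 0).
#' @param rel_tol Relative quadrature tolerance.
#' @return Dimensionless field value(s); multiply by `t2` for degrees C.
#'   Equals pi at the ring axis (`ra = 0`, `za = z0a`).
#' @seealso [ring_shape_surface()] for the elliptic closed form at
#'   `za = z0a = 0`.
#' @examples
#' ring_shape_integral(0)        # pi
#' ring_shape_integral(0.25)
#' @export
ring_shape_integral <- function(ra, za = 0, z0a = 0, rel_tol = 1e-10) {
  stopifnot(length(za) == 1L, length(z0a) == 1L, is.finite(za),
            is.finite(z0a))
  ra <- as.numeric(ra)
  if (any(!is.finite(ra) | ra < 0)) {
    validation_error("ra", "must be finite and >= 0")
  }
  if (z0a < 0) validation_error("z0a", "must be >= 0")
  w2 <- 4 * (za - z0a)^2
  if (any(abs(ra - 0.5) < 1e-6) && abs(za - z0a) < 1e-6) {
    singular_point_error(paste(
      "field point lies on the ring wire (r = a/2, z = z0),",
      "a logarithmic singularity of the ideal line source"
    ))
  }
  vapply(ra, function(r1) {
    A <- 1 + (2 * r1)^2 + w2
    B <- 4 * r1
    res <- stats::integrate(
      function(phi) 1 / sqrt(A - B * cos(phi)),
      0, pi, rel.tol = rel_tol, abs.tol = 0,
      subdivisions = 400L, stop.on.error = FALSE
    )
    if (!res$message %in% c("OK", "roundoff error was detected")) {
      convergence_error(
        sprintf("ring quadrature failed at ra = %g: %s", r1, res$message),
        estimate = res$abs.error
      )
    }
    res$value
  }, numeric(1L))
}

#' Ring shape function on the surface (elliptic closed form)
#'
#' Exact reduction of the angular integral at `za = z0a = 0`:
#' `(2/(1+u)) K(2 sqrt(u)/(1+u))` with `u = 2 ra`. Valid strictly inside the
#' ring (`0 <= ra < 1/2`); the value grows without bound (logarithmically)
#' as `ra -> 1/2`. Outside that range the standoff matters and the caller is
#' directed to [ring_shape_integral()] with an explicit `z0a`.
#'
#' @param ra Radial coordinate in units of a, `0 <= ra < 1/2`. Vectorized.
#' @return Dimensionless field value(s); equals pi at `ra = 0`, monotone
#'   increasing in `ra`.
#' @examples
#' ring_shape_surface(0)     # pi
#' ring_shape_surface(0.25)
#' @export
ring_shape_surface <- function(ra) {
  ra <- as.numeric(ra)
  if (any(!is.finite(ra) | ra < 0)) {
    validation_error("ra", "must be finite and >= 0")
  }
  if (any(ra >= 0.5)) {
    out_of_validity_error(paste(
      "the surface closed form holds only inside the ring (ra < 1/2);",
      "use ring_shape_integral() with an explicit z0a instead"
    ))
  }
  u <- 2 * ra
  (2 / (1 + u)) * elliptic_K(2 * sqrt(u) / (1 + u))
}
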