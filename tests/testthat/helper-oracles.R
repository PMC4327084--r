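# Independent brute-force oracles, deliberately dumb: plain Riemann /
# trapezoid summation, no adaptive machinery shared with the package.

# semi-analytic brute force for the square-sheet potential: the inner
# xi-integral in elementary asinh form, midpoint-summed over eta. The 1/R
# singularity of on-sheet surface points reduces to an integrable log in
# eta that the midpoint rule never samples exactly. Independent of both
# package routes (fully adaptive 2-D quadrature; 4-corner closed form).
oracle_square_midpoint <- function(xa, ya, za, n = 1e6) {
  h <- 1 / n
  eta <- seq(-0.5 + h / 2, 0.5 - h / 2, length.out = n)
  c_ <- sqrt((ya - eta)^2 + za^2)
  g <- asinh((0.5 - xa) / c_) + asinh((0.5 + xa) / c_)
  sum(g) * h
}

# plain trapezoid rule for the ring angular integral
oracle_ring_trapezoid <- function(ra, za = 0, z0a = 0, n = 1e6) {
  phi <- seq(0, pi, length.out = n + 1L)
  f <- 1 / sqrt(1 + (2 * ra)^2 - 4 * ra * cos(phi) + 4 * (za - z0a)^2)
  h <- pi / n
  h * (sum(f) - (f[1L] + f[n + 1L]) / 2)
}

# elliptic reduction of the ring integral at za = z0a, independent route:
# K via direct quadrature of its defining integral (not the package AGM)
oracle_ring_elliptic <- function(u) {
  k <- 2 * sqrt(u) / (1 + u)
  K <- stats::integrate(function(th) 1 / sqrt(1 - k^2 * sin(th)^2),
                        0, pi / 2, rel.tol = 1e-12, abs.tol = 0)$value
  2 / (1 + u) * K
}

reference_scales <- function() thermal_scales(t1 = 0.65, t2 = 0.5)

# axes guaranteed free of the z0a = 0 wire singularity (max radius < 1/2)
wire_free_axis <- function(n = 41L) seq(-0.35, 0.35, length.out = n)
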