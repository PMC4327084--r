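test_that("total surface field superposes the two kernels", {
  ax <- wire_free_axis(21)
  sc <- reference_scales()
  g <- total_surface_field(sc, z0a = 0, x_axis = ax, y_axis = ax)
  # center: 0.65 * 4 log(1+sqrt(2)) + 0.5 * pi, both kernels exact there
  expect_equal(g$values[11, 11], 0.65 * 4 * log(1 + sqrt(2)) + 0.5 * pi,
               tolerance = 1e-10)
  # t2 = 0 reduces to the square field exactly
  g_sq <- total_surface_field(thermal_scales(1, 0), z0a = 0,
                              x_axis = ax, y_axis = ax)
  expect_equal(g_sq$values,
               outer(ax, ax, function(y, x) square_shape_surface(x, y)),
               tolerance = 1e-14)
  # linearity: field(2 t1, 2 t2) = 2 field(t1, t2) pointwise
  g2 <- total_surface_field(thermal_scales(2 * sc$t1, 2 * sc$t2), z0a = 0,
                            x_axis = ax, y_axis = ax)
  expect_equal(g2$values, 2 * g$values, tolerance = 1e-14)
})

test_that("grid nodes on the wire are reported with their location", {
  sc <- reference_scales()
  err <- tryCatch(
    total_surface_field(sc, z0a = 0,
                        x_axis = c(-0.5, -0.25, 0, 0.25, 0.5),
                        y_axis = c(-0.4, -0.3, 0, 0.3)),
    thermofield_singular_point_error = function(e) conditionMessage(e)
  )
  expect_match(err, "grid node")
  expect_match(err, "x = ")
})

test_that("axis profile returns both contributions with the right shape", {
  sc <- reference_scales()
  s <- seq(-0.45, 0.45, length.out = 91)
  p <- axis_profile(sc, z0a = 0, s_values = s)
  expect_named(p, c("s", "dT1", "dT2", "dT_total"))
  expect_equal(p$dT_total, p$dT1 + p$dT2, tolerance = 1e-15)
  i0 <- which(s == 0)
  # square part maximal at the center, ring part minimal inside the ring
  expect_equal(which.max(p$dT1), i0)
  expect_equal(which.min(p$dT2), i0)
  # symmetry dT(s) = dT(-s)
  expect_equal(p$dT_total, rev(p$dT_total), tolerance = 1e-12)
  # x and y axes are equivalent
  py <- axis_profile(sc, z0a = 0, axis = "y", s_values = s)
  expect_equal(p$dT_total, py$dT_total, tolerance = 1e-12)
})

test_that("isotherms of a pure ring field are circles at the right radius", {
  ax <- seq(-1, 1, length.out = 121)
  g <- total_surface_field(thermal_scales(0, 1), z0a = 0.02,
                           x_axis = ax, y_axis = ax)
  level <- 3.4   # between center pi and the near-wire maximum
  iso <- extract_isotherms(g, levels = level)
  expect_length(iso$contours, 1)
  expect_gte(length(iso$contours[[1]]), 2)  # inner and outer circle
  for (ct in iso$contours[[1]]) {
    r <- sqrt(ct$x^2 + ct$y^2)
    expect_lt(stats::sd(r) / mean(r), 0.01)
    # analytic level radius by bisection on the radial kernel
    lo <- if (mean(r) < 0.5) 0 else 0.501
    hi <- if (mean(r) < 0.5) 0.499 else 2
    root <- stats::uniroot(
      function(ra) ring_shape_integral(ra, 0, 0.02) - level, c(lo, hi),
      tol = 1e-10
    )$root
    expect_equal(mean(r), root, tolerance = 0.005)
  }
})

test_that("isotherm levels outside the range yield warnings, not contours", {
  ax <- wire_free_axis(21)
  g <- total_surface_field(reference_scales(), z0a = 0, x_axis = ax, y_axis = ax)
  mid <- mean(range(g$values))
  iso <- extract_isotherms(g, levels = c(1e6, mid))
  expect_length(iso$contours[[1]], 0)
  expect_match(iso$warnings, "outside", all = FALSE)
  expect_gt(length(iso$contours[[2]]), 0)
})

test_that("contour vertices re-interpolate to their level", {
  ax <- seq(-1, 1, length.out = 121)
  g <- total_surface_field(thermal_scales(0.65, 0.5), z0a = 0.02,
                           x_axis = ax, y_axis = ax)
  center <- g$values[61, 61]
  iso <- extract_isotherms(g, levels = 0.95 * center)
  expect_length(iso$contours[[1]], 1)  # single closed curve around the origin
  ct <- iso$contours[[1]][[1]]
  expect_equal(ct$x[1], ct$x[nrow(ct)], tolerance = 1e-9)  # closed
  rng <- diff(range(g$values))
  vals <- thermofield:::interp_field(g, ct$x, ct$y)
  expect_lt(max(abs(vals - 0.95 * center)) / rng, 1e-6)
})

test_that("homogeneity report behaves on grids and callables", {
  f <- function(x, y) {
    0.65 * square_shape_surface(x, y) +
      0.5 * ring_shape_surface(sqrt(x^2 + y^2))
  }
  rep_f <- homogeneity_report(f, probe_radius = 0.2, epsilon = 0.1)
  expect_equal(rep_f$center_value, f(0, 0))
  expect_equal(rep_f$homogeneous_area_fraction, 1)  # measured flat to < 0.01
  expect_lt(rep_f$max_abs_deviation, 0.01)

  # epsilon = Inf always gives fraction 1 (square-only field)
  f_sq <- function(x, y) square_shape_surface(x, y)
  expect_equal(
    homogeneity_report(f_sq, probe_radius = 0.2,
                       epsilon = Inf)$homogeneous_area_fraction, 1
  )

  # max deviation is non-decreasing in probe radius (nested suprema)
  d1 <- homogeneity_report(f_sq, probe_radius = 0.1)$max_abs_deviation
  d2 <- homogeneity_report(f_sq, probe_radius = 0.2)$max_abs_deviation
  d3 <- homogeneity_report(f_sq, probe_radius = 0.3)$max_abs_deviation
  expect_true(d1 <= d2 && d2 <= d3)

  # grid route agrees with the callable route to grid resolution
  ax <- wire_free_axis(141)
  g <- total_surface_field(reference_scales(), z0a = 0, x_axis = ax, y_axis = ax)
  rep_g <- homogeneity_report(g, probe_radius = 0.2, epsilon = 0.1)
  expect_equal(rep_g$center_value, rep_f$center_value, tolerance = 1e-9)
  expect_equal(rep_g$max_abs_deviation, rep_f$max_abs_deviation,
               tolerance = 0.1)
  # a grid with no node inside the probe disc is an error
  ax0 <- c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3)  # origin not a node
  g0 <- total_surface_field(reference_scales(), z0a = 0, x_axis = ax0, y_axis = ax0)
  expect_error(homogeneity_report(g0, probe_radius = 1e-6),
               class = "thermofield_validation_error")
})

test_that("CSV exports round-trip through read.csv", {
  ax <- wire_free_axis(11)
  g <- total_surface_field(reference_scales(), z0a = 0, x_axis = ax, y_axis = ax)
  long <- tempfile(fileext = ".csv")
  write_field_csv(g, long, "long")
  df <- utils::read.csv(long)
  expect_named(df, c("x", "y", "delta_T_C"))
  expect_equal(nrow(df), 121)
  expect_equal(df$delta_T_C[df$x == 0 & df$y == 0], g$values[6, 6],
               tolerance = 1e-8)

  mat <- tempfile(fileext = ".csv")
  write_field_csv(g, mat, "matrix")
  expect_equal(length(readLines(mat)), 12)

  iso <- extract_isotherms(g, levels = mean(range(g$values)))
  isof <- tempfile(fileext = ".csv")
  write_isotherms_csv(iso, isof)
  di <- utils::read.csv(isof)
  expect_named(di, c("level_C", "contour_id", "vertex_id", "x", "y"))
  expect_gt(nrow(di), 0)
})
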