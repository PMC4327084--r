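# Superposed surface field, isotherms and homogeneity metrics.

#' Total surface temperature-increase field on a grid
#'
#' Superposes the square-sheet and ring kernels on a regular surface grid:
#' `values[i, j] = t1 * F_square(x_j, y_i) + t2 * G_ring(r_ij; z0a)`, linear
#' in `(t1, t2)`. Coordinates are in units of the square side a. The ring
#' part is evaluated once per unique radius (the grid typically has ~n^2/8
#' of them), which keeps a 201 x 201 grid fast. Grid nodes falling exactly
#' on the four sheet corners (where the surface closed form is degenerate
#' but the field itself is finite) are patched with the quadrature route.
#'
#' @param scales A [thermal_scales()].
#' @param z0a Ring standoff in units of a. The default 0.02 satisfies the
#'   near-surface regime z0 << a and keeps grid nodes at radius 1/2 off the
#'   wire singularity; with `z0a = 0` any node at exact radius 1/2 raises a
#'   singular-point error reporting its grid location.
#' @param x_axis,y_axis Strictly increasing coordinate vectors in units of
#'   a. Default: 201 nodes over \[-1, 1\] (node-centered, origin included).
#' @param rel_tol Quadrature tolerance for the ring kernel.
#' @return A `tf_field_grid`: list with `x_axis`, `y_axis`, `values`
#'   (matrix of temperature increments in degrees C, rows indexed by y,
#'   columns by x) and `meta` (scales and z0a used).
#' @examples
#' g <- total_surface_field(thermal_scales(0.65, 0.5),
#'                          x_axis = seq(-0.4, 0.4, length.out = 41),
#'                          y_axis = seq(-0.4, 0.4, length.out = 41))
#' g$values[21, 21]   # center value
#' @export
total_surface_field <- function(scales, z0a = 0.02,
                                x_axis = seq(-1, 1, length.out = 201L),
                                y_axis = seq(-1, 1, length.out = 201L),
                                rel_tol = 1e-10) {
  stopifnot(inherits(scales, "tf_thermal_scales"))
  if (any(diff(x_axis) <= 0)) validation_error("x_axis", "must be strictly increasing")
  if (any(diff(y_axis)  <= 0)) validation_error("y_axis", "must be strictly increasing")

  zero_mat <- matrix(0, nrow = length(y_axis), ncol = length(x_axis))

  sq <- zero_mat
  if (scales$t1 != 0) {
    # the surface closed form is degenerate exactly at the four sheet
    # corners, where the field itself is finite (the 1/R singularity is
    # integrable); patch those nodes with the quadrature route
    corner <- outer(abs(y_axis) == 0.5, abs(x_axis) == 0.5, "&")
    sq <- outer(y_axis, x_axis, function(y, x) {
      out <- numeric(length(x))
      reg <- !(abs(x) == 0.5 & abs(y) == 0.5)
      out[reg] <- square_shape_surface(x[reg], y[reg])
      out
    })
    if (any(corner)) {
      idx <- which(corner, arr.ind = TRUE)
      sq[corner] <- vapply(seq_len(nrow(idx)), function(k) {
        square_shape_quadrature(x_axis[idx[k, 2L]], y_axis[idx[k, 1L]], 0,
                                rel_tol = 1e-9)
      }, numeric(1L))
    }
  }

  rg <- zero_mat
  if (scales$t2 != 0) {
    r_mat <- sqrt(outer(y_axis^2, x_axis^2, "+"))
    r_unique <- unique(as.vector(r_mat))
    ring_u <- vapply(r_unique, function(r1) {
      tryCatch(
        ring_shape_integral(r1, za = 0, z0a = z0a, rel_tol = rel_tol),
        thermofield_singular_point_error = function(e) {
          idx <- which(r_mat == r1, arr.ind = TRUE)[1L, ]
          singular_point_error(sprintf(
            "grid node (x = %g, y = %g) lies on the ring wire: %s",
            x_axis[idx[2L]], y_axis[idx[1L]], conditionMessage(e)
          ))
        }
      )
    }, numeric(1L))
    rg <- matrix(ring_u[match(as.vector(r_mat), r_unique)],
                 nrow = length(y_axis))
  }

  structure(
    list(
      x_axis = x_axis,
      y_axis = y_axis,
      values = scales$t1 * sq + scales$t2 * rg,
      meta = list(scales = scales, z0a = z0a, rel_tol = rel_tol)
    ),
    class = "tf_field_grid"
  )
}

#' @export
print.tf_field_grid <- function(x, ...) {
  cat(sprintf(
    "Surface field grid: %d x %d nodes over [%g, %g] x [%g, %g] (units of a)\n",
    length(x$x_axis), length(x$y_axis),
    min(x$x_axis), max(x$x_axis), min(x$y_axis), max(x$y_axis)
  ))
  cat(sprintf("  t1 = %g, t2 = %g degC, z0a = %g; dT range [%.4g, %.4g] degC\n",
              x$meta$scales$t1, x$meta$scales$t2, x$meta$z0a,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Axis profile of the two contributions and their sum
#'
#' Evaluates the separate square and ring contributions and the total
#' temperature increase along the x (or y) axis: the standard way to
#' visualize how the ring's central minimum fills in the square's fall-off
#' to produce a quasi-homogeneous plateau.
#'
#' @inheritParams total_surface_field
#' @param axis `"x"` or `"y"` (the two are identical by symmetry; both are
#'   offered for plotting convenience).
#' @param s_values Positions along the axis, units of a.
#' @return A data.frame with columns `s`, `dT1`, `dT2`, `dT_total` (degrees
#'   C).
#' @examples
#' axis_profile(thermal_scales(0.65, 0.5), z0a = 0,
#'              s_values = seq(-0.4, 0.4, by = 0.1))
#' @export
axis_profile <- function(scales, z0a = 0.02, axis = c("x", "y"),
                         s_values = seq(-1, 1, length.out = 201L),
                         rel_tol = 1e-10) {
  stopifnot(inherits(scales, "tf_thermal_scales"))
  axis <- match.arg(axis)
  s <- as.numeric(s_values)
  if (any(!is.finite(s))) validation_error("s_values", "must be finite")
  sq <- if (axis == "x") square_shape_surface(s, 0) else square_shape_surface(0, s)
  rg <- ring_shape_integral(abs(s), za = 0, z0a = z0a, rel_tol = rel_tol)
  data.frame(
    s = s,
    dT1 = scales$t1 * sq,
    dT2 = scales$t2 * rg,
    dT_total = scales$t1 * sq + scales$t2 * rg
  )
}

#' Extract isotherms from a field grid
#'
#' Level curves of the surface temperature increase, via marching squares
#' with linear edge interpolation (grDevices::contourLines). Levels outside
#' the grid's value range produce an empty contour list and are recorded in
#' the returned object's `warnings`.
#'
#' @param grid A `tf_field_grid`.
#' @param levels Temperature-increase levels, degrees C.
#' @return A `tf_isotherm_set`: list with `levels`, `contours` (per level, a
#'   list of data.frames with columns `x`, `y`) and `warnings` (character).
#' @examples
#' g <- total_surface_field(thermal_scales(0.65, 0.5),
#'                          x_axis = seq(-0.45, 0.45, length.out = 61),
#'                          y_axis = seq(-0.45, 0.45, length.out = 61),
#'                          z0a = 0)
#' iso <- extract_isotherms(g, levels = 0.95 * g$values[31, 31])
#' length(iso$contours[[1]])
#' @export
extract_isotherms <- function(grid, levels) {
  stopifnot(inherits(grid, "tf_field_grid"))
  levels <- as.numeric(levels)
  if (any(!is.finite(levels))) validation_error("levels", "must be finite")
  lo <- min(grid$values)
  hi <- max(grid$values)
  warnings <- character(0)
  contours <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    lv <- levels[k]
    if (lv <= lo || lv >= hi) {
      warnings <- c(warnings, sprintf(
        "level %g degC outside the open grid range (%g, %g); no contours",
        lv, lo, hi
      ))
      contours[[k]] <- list()
      next
    }
    # contourLines expects z[i, j] at (x[i], y[j]); our values are [y, x]
    cl <- grDevices::contourLines(
      x = grid$x_axis, y = grid$y_axis, z = t(grid$values), levels = lv
    )
    contours[[k]] <- lapply(cl, function(p) data.frame(x = p$x, y = p$y))
  }
  structure(
    list(levels = levels, contours = contours, warnings = warnings),
    class = "tf_isotherm_set"
  )
}

#' @export
print.tf_isotherm_set <- function(x, ...) {
  cat(sprintf("Isotherm set: %d level(s)\n", length(x$levels)))
  for (k in seq_along(x$levels)) {
    cat(sprintf("  %g degC: %d contour(s)\n",
                x$levels[k], length(x$contours[[k]])))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

# bilinear interpolation of a field grid at arbitrary points
interp_field <- function(grid, x, y) {
  xi <- findInterval(x, grid$x_axis, rightmost.closed = TRUE)
  yi <- findInterval(y, grid$y_axis, rightmost.closed = TRUE)
  if (any(xi < 1L | xi >= length(grid$x_axis) + 1L) ||
      any(yi < 1L | yi >= length(grid$y_axis) + 1L)) {
    validation_error("x/y", "interpolation point outside the grid")
  }
  xi <- pmin(xi, length(grid$x_axis) - 1L)
  yi <- pmin(yi, length(grid$y_axis) - 1L)
  x0 <- grid$x_axis[xi]; x1 <- grid$x_axis[xi + 1L]
  y0 <- grid$y_axis[yi]; y1 <- grid$y_axis[yi + 1L]
  tx <- (x - x0) / (x1 - x0)
  ty <- (y - y0) / (y1 - y0)
  v00 <- grid$values[cbind(yi, xi)]
  v01 <- grid$values[cbind(yi, xi + 1L)]
  v10 <- grid$values[cbind(yi + 1L, xi)]
  v11 <- grid$values[cbind(yi + 1L, xi + 1L)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Quantify the homogeneity of the central heating zone
#'
#' Measures how flat the combined field is over the central probe disc
#' where the sensor cells sit: the maximum absolute deviation from the
#' exact center value, and the fraction of probed locations within
#' `+/- epsilon` of it.
#'
#' @param field Either a `tf_field_grid` (the probe uses its nodes inside
#'   the disc, with the center value obtained by bilinear interpolation at
#'   the origin) or a function `f(x, y)` returning the field in degrees C
#'   (probed on a polar mesh; the center is the exact evaluation `f(0, 0)`).
#' @param probe_radius Radius of the probe disc, units of a (default 0.2).
#' @param epsilon Homogeneity tolerance, degrees C (default 0.1).
#' @param n_r,n_theta Polar probe resolution when `field` is a function.
#' @return A `tf_homogeneity_report`: list with `center_value`,
#'   `max_abs_deviation`, `probe_radius`, `epsilon`,
#'   `homogeneous_area_fraction`.
#' @examples
#' f <- function(x, y) 0.65 * square_shape_surface(x, y) +
#'   0.5 * ring_shape_surface(sqrt(x^2 + y^2))
#' homogeneity_report(f, probe_radius = 0.2, epsilon = 0.1)
#' @export
homogeneity_report <- function(field, probe_radius = 0.2, epsilon = 0.1,
                               n_r = 25L, n_theta = 32L) {
  check_scalar(probe_radius, "probe_radius")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0) {
    validation_error("epsilon", "must be a positive number (Inf allowed)")
  }
  if (inherits(field, "tf_field_grid")) {
    r_mat <- sqrt(outer(field$y_axis^2, field$x_axis^2, "+"))
    inside <- r_mat <= probe_radius
    if (!any(inside)) {
      validation_error("probe_radius",
                       "probe disc contains no grid nodes")
    }
    center <- interp_field(field, 0, 0)
    vals <- field$values[inside]
  } else if (is.function(field)) {
    center <- field(0, 0)
    rr <- seq(0, probe_radius, length.out = n_r + 1L)[-1L]
    th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
    px <- as.vector(outer(rr, th, function(r, t) r * cos(t)))
    py <- as.vector(outer(rr, th, function(r, t) r * sin(t)))
    vals <- mapply(field, px, py)
  } else {
    validation_error("field", "must be a tf_field_grid or a function(x, y)")
  }
  dev <- abs(vals - center)
  structure(
    list(
      center_value = center,
      max_abs_deviation = max(dev),
      probe_radius = probe_radius,
      epsilon = epsilon,
      homogeneous_area_fraction = mean(dev <= epsilon)
    ),
    class = "tf_homogeneity_report"
  )
}

#' @export
print.tf_homogeneity_report <- function(x, ...) {
  cat(sprintf(
    paste0("Homogeneity over disc r <= %g a:\n",
           "  center dT        = %.6g degC\n",
           "  max |deviation|  = %.6g degC\n",
           "  within +/- %g degC: %.1f%% of probed area\n"),
    x$probe_radius, x$center_value, x$max_abs_deviation,
    x$epsilon, 100 * x$homogeneous_area_fraction
  ))
  invisible(x)
}

#' Export a field grid to CSV
#'
#' @param grid A `tf_field_grid`.
#' @param path Output file path.
#' @param format `"long"` (header `x,y,delta_T_C`, one node per row) or
#'   `"matrix"` (first column y, remaining columns the x axis). Values are
#'   written with 9 significant digits.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(grid, path, format = c("long", "matrix")) {
  stopifnot(inherits(grid, "tf_field_grid"))
  format <- match.arg(format)
  fmt <- function(v) formatC(v, digits = 9, format = "g")
  if (format == "long") {
    df <- expand.grid(x = grid$x_axis, y = grid$y_axis,
                      KEEP.OUT.ATTRS = FALSE)
    df$delta_T_C <- as.vector(t(grid$values))
    lines <- c("x,y,delta_T_C",
               paste(fmt(df$x), fmt(df$y), fmt(df$delta_T_C), sep = ","))
  } else {
    header <- paste(c("y\\x", fmt(grid$x_axis)), collapse = ",")
    rows <- vapply(seq_along(grid$y_axis), function(i) {
      paste(c(fmt(grid$y_axis[i]), fmt(grid$values[i, ])), collapse = ",")
    }, character(1L))
    lines <- c(header, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export an isotherm set to CSV
#'
#' Header `level_C,contour_id,vertex_id,x,y`; 9 significant digits.
#'
#' @param iso A `tf_isotherm_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotherms_csv <- function(iso, path) {
  stopifnot(inherits(iso, "tf_isotherm_set"))
  fmt <- function(v) formatC(v, digits = 9, format = "g")
  lines <- "level_C,contour_id,vertex_id,x,y"
  for (k in seq_along(iso$levels)) {
    for (cid in seq_along(iso$contours[[k]])) {
      p <- iso$contours[[k]][[cid]]
      lines <- c(lines, paste(
        fmt(iso$levels[k]), cid, seq_len(nrow(p)), fmt(p$x), fmt(p$y),
        sep = ","
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
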