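# Heater geometry, electrical parameters and thermal scale temperatures.
#
# The physics works in dimensionless coordinates (lengths in units of the
# square side a, temperatures as increments above the baseline T0). The
# objects here hold the SI-unit inputs and reduce them to the two scale
# temperatures t1 (square sheet) and t2 (O-ring) that multiply the
# dimensionless field shapes.

validation_error <- function(field, msg) {
  stop(errorCondition(
    sprintf("invalid `%s`: %s", field, msg),
    field = field,
    class = c("thermofield_validation_error", "error", "condition")
  ))
}

check_scalar <- function(x, name, positive = TRUE, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    validation_error(name, "must be a single finite number")
  }
  if (positive && x <= 0) validation_error(name, "must be > 0")
  if (!is.null(min) && x < min) {
    validation_error(name, sprintf("must be >= %g", min))
  }
  as.numeric(x)
}

thin_layer_warning <- function(msg) {
  warning(warningCondition(
    msg, class = c("thermofield_thin_layer_warning", "warning", "condition")
  ))
}

#' Two half-space media
#'
#' The heater sits at the plane interface between two semi-infinite
#' homogeneous media: air above (`kappa_e`) and biological tissue below
#' (`kappa_i`). Only the sum `kappa_e + kappa_i` enters the stationary
#' interface kernel, so swapping the two media leaves all fields unchanged.
#'
#' @param kappa_e Thermal conductivity of the upper medium (air),
#'   W m^-1 K^-1. Must be > 0.
#' @param kappa_i Thermal conductivity of the lower medium (tissue),
#'   W m^-1 K^-1. Must be > 0.
#' @return An object of class `tf_media`.
#' @examples
#' media(kappa_e = 0.026, kappa_i = 0.5)
#' @export
media <- function(kappa_e, kappa_i) {
  structure(
    list(
      kappa_e = check_scalar(kappa_e, "kappa_e"),
      kappa_i = check_scalar(kappa_i, "kappa_i")
    ),
    class = "tf_media"
  )
}

#' Square plane heater
#'
#' A thin square conductive layer of side `a` and thickness `d`, driven by a
#' voltage `U` between electrodes on two opposite sides, which makes the
#' current (and hence the Joule heat density) homogeneous over the square.
#'
#' @param a Side length, m.
#' @param d Conductive layer thickness, m. The model assumes a thin layer;
#'   `d/a >= 0.1` raises a validation warning (class
#'   `thermofield_thin_layer_warning`), not an error.
#' @param rho Specific resistance of the layer material, Ohm m.
#' @param U Voltage between the lateral electrodes, V.
#' @return An object of class `tf_square_heater`.
#' @examples
#' square_heater(a = 0.04, d = 1e-4, rho = 10, U = 2)
#' @export
square_heater <- function(a, d, rho, U) {
  obj <- structure(
    list(
      a = check_scalar(a, "a"),
      d = check_scalar(d, "d"),
      rho = check_scalar(rho, "rho"),
      U = check_scalar(U, "U")
    ),
    class = "tf_square_heater"
  )
  if (obj$d / obj$a >= 0.1) {
    thin_layer_warning(sprintf(
      "d/a = %.3g violates the thin-layer assumption d/a < 0.1", obj$d / obj$a
    ))
  }
  obj
}

#' O-ring wire heater
#'
#' An ideal circular line source of diameter equal to the square side `a`
#' (radius a/2), suspended a small standoff `z0` above the interface. The
#' ring field is minimal at the circle center, which is what lets it
#' compensate the square heater's central maximum.
#'
#' @param a Ring diameter (equal to the square heater side), m.
#' @param z0 Standoff of the ring plane above the interface, m. The model is
#'   derived for `z0 << a`; `z0/a >= 0.1` raises a validation warning.
#' @param S Conductor cross-section area, m^2.
#' @param R_total Total ring resistance, Ohm.
#' @param U Voltage across the ring, V.
#' @return An object of class `tf_ring_heater`.
#' @examples
#' ring_heater(a = 0.04, z0 = 5e-4, S = 1e-8, R_total = 2, U = 1)
#' @export
ring_heater <- function(a, z0, S, R_total, U) {
  obj <- structure(
    list(
      a = check_scalar(a, "a"),
      z0 = check_scalar(z0, "z0"),
      S = check_scalar(S, "S"),
      R_total = check_scalar(R_total, "R_total"),
      U = check_scalar(U, "U")
    ),
    class = "tf_ring_heater"
  )
  if (obj$z0 / obj$a >= 0.1) {
    thin_layer_warning(sprintf(
      "z0/a = %.3g violates the near-surface assumption z0/a < 0.1",
      obj$z0 / obj$a
    ))
  }
  obj
}

#' Thermal scales
#'
#' Baseline temperature and the two scale temperatures that multiply the
#' dimensionless field shapes: the total surface temperature is
#' `T0 + t1 * F_square(x/a, y/a) + t2 * F_ring(r/a)`. This is the canonical
#' interface of the field modules; electrical parameters only enter through
#' [thermal_scale_t1()] and [thermal_scale_t2()].
#'
#' @param t1 Square-source scale temperature, degrees C (>= 0).
#' @param t2 Ring-source scale temperature, degrees C (>= 0).
#' @param T0 Baseline medium temperature, degrees C. Carried along for
#'   reporting absolute temperatures; the field physics never depends on it.
#' @return An object of class `tf_thermal_scales`.
#' @examples
#' thermal_scales(t1 = 0.65, t2 = 0.5, T0 = 39)
#' @export
thermal_scales <- function(t1, t2, T0 = 0) {
  if (!is.numeric(T0) || length(T0) != 1L || !is.finite(T0)) {
    validation_error("T0", "must be a single finite number")
  }
  structure(
    list(
      T0 = as.numeric(T0),
      t1 = check_scalar(t1, "t1", positive = FALSE, min = 0),
      t2 = check_scalar(t2, "t2", positive = FALSE, min = 0)
    ),
    class = "tf_thermal_scales"
  )
}

#' @export
print.tf_thermal_scales <- function(x, ...) {
  cat(sprintf(
    "Thermal scales: T0 = %g degC, t1 = %g degC, t2 = %g degC\n",
    x$T0, x$t1, x$t2
  ))
  invisible(x)
}

#' Current density in the square layer
#'
#' Magnitude of the homogeneous volumetric current density `j = U/(a rho)`
#' driven between the lateral electrodes; directed along the x axis by
#' convention.
#'
#' @param square A [square_heater()].
#' @return Current density, A m^-2.
#' @export
current_density <- function(square) {
  stopifnot(inherits(square, "tf_square_heater"))
  square$U / (square$a * square$rho)
}

#' Volumetric heat density of the square layer
#'
#' Joule heating `Q1 = j E = U^2 / (a^2 rho)` dissipated per unit volume of
#' the conductive layer.
#'
#' @inheritParams current_density
#' @return Q1, W m^-3.
#' @export
square_power_density <- function(square) {
  stopifnot(inherits(square, "tf_square_heater"))
  square$U^2 / (square$a^2 * square$rho)
}

#' Volumetric heat density of the ring conductor
#'
#' `Q2 = U^2 / (pi R a S)`. `Q2 * S` is the dissipated power per unit length
#' of the wire, and `Q2 * S * pi * a = U^2/R` recovers the total ring power.
#'
#' @param ring A [ring_heater()].
#' @return Q2, W m^-3.
#' @export
ring_power_density <- function(ring) {
  stopifnot(inherits(ring, "tf_ring_heater"))
  ring$U^2 / (pi * ring$R_total * ring$a * ring$S)
}

#' Square-source scale temperature
#'
#' `t1 = Q1 d a / (2 pi (kappa_e + kappa_i))`: the temperature increment
#' multiplying the dimensionless square-sheet shape. Homogeneous of degree 2
#' in the drive voltage.
#'
#' @inheritParams current_density
#' @param med A [media()].
#' @return t1, degrees C.
#' @export
thermal_scale_t1 <- function(square, med) {
  stopifnot(inherits(med, "tf_media"))
  q1 <- square_power_density(square)
  q1 * square$d * square$a / (2 * pi * (med$kappa_e + med$kappa_i))
}

#' Ring-source scale temperature
#'
#' `t2 = Q2 S / (pi (kappa_e + kappa_i))`. Independent of the standoff z0,
#' which only shifts the shape function.
#'
#' @inheritParams ring_power_density
#' @param med A [media()].
#' @return t2, degrees C.
#' @export
thermal_scale_t2 <- function(ring, med) {
  stopifnot(inherits(med, "tf_media"))
  q2 <- ring_power_density(ring)
  q2 * ring$S / (pi * (med$kappa_e + med$kappa_i))
}

#' Reduce heater electrical parameters to thermal scales
#'
#' Convenience constructor combining [thermal_scale_t1()] and
#' [thermal_scale_t2()] into a [thermal_scales()] object.
#'
#' @inheritParams thermal_scale_t1
#' @inheritParams thermal_scale_t2
#' @param T0 Baseline temperature, degrees C.
#' @return A `tf_thermal_scales`.
#' @export
scales_from_heaters <- function(square, ring, med, T0 = 0) {
  thermal_scales(
    t1 = thermal_scale_t1(square, med),
    t2 = thermal_scale_t2(ring, med),
    T0 = T0
  )
}
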