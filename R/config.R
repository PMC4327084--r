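# JSON configuration handling. A config describes the two heaters either
# electrically (media + square + ring blocks) or directly through the
# thermal scales; exactly one parameterization must be present per heater.

config_error <- function(key, msg) {
  stop(errorCondition(
    sprintf("config: `%s` %s", key, msg),
    key = key,
    class = c("thermofield_config_error", "thermofield_validation_error",
              "error", "condition")
  ))
}

.need_num <- function(cfg, key) {
  v <- cfg
  for (part in strsplit(key, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(v) || is.null(v[[part]])) config_error(key, "is missing")
    v <- v[[part]]
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    config_error(key, "must be a single finite number")
  }
  as.numeric(v)
}

#' Load and validate a heater configuration
#'
#' Reads a flat JSON config and reduces it to the canonical (thermal
#' scales, z0a) parameterization. Two forms are accepted:
#' \describe{
#'   \item{electrical}{keys `kappa_e`, `kappa_i`, `square.{a,d,rho,U}`,
#'     `ring.{z0,S,R,U}`; the ring diameter equals the square side and
#'     `z0a = ring.z0 / square.a`. `T0` optional.}
#'   \item{scales}{key `scales.{t1,t2}` (optionally `scales.T0`) with an
#'     optional top-level `z0a` (default 0.02).}
#' }
#' Supplying both `scales` and an electrical block, or neither, is an
#' error; all errors carry the offending key in their message.
#'
#' @param path Path to the JSON file.
#' @return A list with elements `scales` (a [thermal_scales()]) and `z0a`.
#' @examples
#' cfg <- system.file("extdata", "reference_scales.json", package = "thermofield")
#' load_config(cfg)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_error(path, "config file not found")
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  has_scales <- !is.null(cfg$scales)
  has_elec <- !is.null(cfg$square) || !is.null(cfg$ring) ||
    !is.null(cfg$kappa_e) || !is.null(cfg$kappa_i)
  if (has_scales && has_elec) {
    config_error("scales", "and electrical parameters are mutually exclusive")
  }
  if (!has_scales && !has_elec) {
    config_error("scales", "or electrical parameters (kappa_e, ...) required")
  }
  if (has_scales) {
    t0 <- if (!is.null(cfg$scales$T0)) .need_num(cfg, "scales.T0") else 0
    sc <- thermal_scales(
      t1 = .need_num(cfg, "scales.t1"),
      t2 = .need_num(cfg, "scales.t2"),
      T0 = t0
    )
    z0a <- if (!is.null(cfg$z0a)) .need_num(cfg, "z0a") else 0.02
    return(list(scales = sc, z0a = z0a))
  }
  med <- media(.need_num(cfg, "kappa_e"), .need_num(cfg, "kappa_i"))
  sq <- square_heater(
    a = .need_num(cfg, "square.a"),
    d = .need_num(cfg, "square.d"),
    rho = .need_num(cfg, "square.rho"),
    U = .need_num(cfg, "square.U")
  )
  rg <- ring_heater(
    a = sq$a,
    z0 = .need_num(cfg, "ring.z0"),
    S = .need_num(cfg, "ring.S"),
    R_total = .need_num(cfg, "ring.R"),
    U = .need_num(cfg, "ring.U")
  )
  t0 <- if (!is.null(cfg$T0)) .need_num(cfg, "T0") else 0
  list(
    scales = scales_from_heaters(sq, rg, med, T0 = t0),
    z0a = rg$z0 / sq$a
  )
}
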