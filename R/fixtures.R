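# Seeded generator of randomized valid parameter sets for testing. The
# physics code itself contains no randomness; all of it lives here.

#' Generate seeded random heater parameter sets
#'
#' Draws `n_cases` physically valid (media, square heater, ring heater)
#' parameter sets uniformly from the given ranges, reproducibly: the same
#' seed yields identical cases, and the caller's RNG state is left
#' untouched. Ranges default to realistic bench values for a skin-contact
#' sensor matrix: centimetre-scale heaters, micrometre-scale layer, air
#' above soft tissue.
#'
#' @param seed Integer seed.
#' @param n_cases Number of cases.
#' @param ranges Named list of `c(min, max)` ranges for `kappa_e`,
#'   `kappa_i`, `a`, `d_over_a`, `rho`, `U1`, `z0_over_a`, `S`, `R_total`,
#'   `U2` (SI units; ratios keep the thin-layer and near-surface
#'   assumptions satisfied by construction).
#' @return A data.frame with one row per case, plus the derived columns
#'   `t1`, `t2` and `z0a`.
#' @examples
#' fixture_cases(seed = 7, n_cases = 3)
#' @export
fixture_cases <- function(seed, n_cases = 10L, ranges = list()) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    validation_error("seed", "must be a single finite number")
  }
  n_cases <- as.integer(check_scalar(n_cases, "n_cases", min = 1))

  defaults <- list(
    kappa_e = c(0.02, 0.03),     # air-like, W/m/K
    kappa_i = c(0.2, 0.6),       # soft tissue, W/m/K
    a = c(0.01, 0.05),           # m
    d_over_a = c(1e-4, 0.05),
    rho = c(1e-6, 1e-4),         # Ohm m (resistive film)
    U1 = c(0.1, 5),              # V
    z0_over_a = c(0.005, 0.05),
    S = c(1e-9, 1e-7),           # m^2 wire cross-section
    R_total = c(0.5, 20),        # Ohm
    U2 = c(0.1, 5)               # V
  )
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown)) {
    validation_error(unknown[1L], "unknown fixture range name")
  }
  rng <- utils::modifyList(defaults, ranges)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  draw <- function(nm) stats::runif(n_cases, rng[[nm]][1L], rng[[nm]][2L])
  df <- data.frame(
    case = seq_len(n_cases),
    kappa_e = draw("kappa_e"),
    kappa_i = draw("kappa_i"),
    a = draw("a"),
    d = NA_real_,
    rho = draw("rho"),
    U1 = draw("U1"),
    z0 = NA_real_,
    S = draw("S"),
    R_total = draw("R_total"),
    U2 = draw("U2")
  )
  df$d <- df$a * draw("d_over_a")
  df$z0 <- df$a * draw("z0_over_a")

  df$t1 <- vapply(seq_len(n_cases), function(i) {
    thermal_scale_t1(
      square_heater(df$a[i], df$d[i], df$rho[i], df$U1[i]),
      media(df$kappa_e[i], df$kappa_i[i])
    )
  }, numeric(1L))
  df$t2 <- vapply(seq_len(n_cases), function(i) {
    thermal_scale_t2(
      ring_heater(df$a[i], df$z0[i], df$S[i], df$R_total[i], df$U2[i]),
      media(df$kappa_e[i], df$kappa_i[i])
    )
  }, numeric(1L))
  df$z0a <- df$z0 / df$a
  df
}
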