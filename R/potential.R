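#' Designed groove potentials
#'
#' The synthetic stand-in for the protein/lipid system is a 3-D potential
#'
#'   U(x, y, z) = U_z(z) + 1/2 * k_r(z) * (x^2 + y^2)
#'
#' where `U_z` is a sum of Gaussian terms along the membrane normal and
#' `k_r(z)` is a harmonic in-plane confinement profile (the groove walls).
#' Because the XY part is Gaussian at every z it integrates analytically,
#' so the exact 1-D free-energy profile along z is
#'
#'   F(z) = U_z(z) + kT * log( k_r(z) / (2 * pi * kT) )
#'
#' ([effective_pmf()]), which is the ground truth used by all recovery
#' tests — no numerics enter the oracle.
#'
#' Three presets mirror the regimes of interest (barrier heights along the
#' permeation coordinate, in kcal/mol, measured as max - min of F over the
#' umbrella-covered range):
#'
#' * `"open_pg"`  — open groove with an anionic lipid present: low barrier,
#'   designed 2.0.
#' * `"open_pc"`  — open groove with a bulky zwitterionic lipid: designed
#'   7.0, peak at z = 2.7 A.
#' * `"l302a"`    — constricted (mutant-like) groove: designed 8.0 with the
#'   peak at z = 3.5 A, realised as a 6.58 kcal/mol energetic term plus an
#'   entropic term from a 10-fold tightening of `k_r` at the neck
#'   (kT * log(10) = 1.418 kcal/mol at 310 K).
#'
#' @param preset one of `"open_pg"`, `"open_pc"`, `"l302a"`, or `"custom"`.
#' @param z_terms for `"custom"`: data frame with columns `amplitude`
#'   (kcal/mol), `center` (A), `width` (A, Gaussian sigma).
#' @param radial for `"custom"`: list with `base_k`, `delta_k`
#'   (kcal/mol/A^2), `center`, `width` (A); `k_r(z) = base_k + delta_k *
#'   exp(-(z - center)^2 / (2 width^2))`.
#' @return object of class `groove_potential`.
#' @export
groove_potential <- function(preset = c("open_pg", "open_pc", "l302a", "custom"),
                             z_terms = NULL, radial = NULL) {
  preset <- match.arg(preset)
  flat_radial <- list(base_k = 0.5, delta_k = 0, center = 0, width = 1)
  if (preset == "open_pg") {
    z_terms <- data.frame(amplitude = 2.0, center = 0.5, width = 2.5)
    radial <- flat_radial
  } else if (preset == "open_pc") {
    z_terms <- data.frame(amplitude = 7.0, center = 2.7, width = 2.5)
    radial <- flat_radial
  } else if (preset == "l302a") {
    # amplitude chosen so the analytic barrier is exactly 8.0 at 310 K:
    # 8.0 - kT*log((0.5 + 4.5)/0.5)
    amp <- 8.0 - kT(310) * log(10)
    z_terms <- data.frame(amplitude = amp, center = 3.5, width = 2.0)
    radial <- list(base_k = 0.5, delta_k = 4.5, center = 3.5, width = 2.0)
  } else {
    if (is.null(z_terms)) {
      z_terms <- data.frame(amplitude = numeric(0), center = numeric(0),
                            width = numeric(0))
    }
    stopifnot(all(c("amplitude", "center", "width") %in% names(z_terms)))
    if (is.null(radial)) radial <- flat_radial
  }
  stopifnot(radial$base_k > 0, radial$base_k + radial$delta_k > 0,
            all(z_terms$width > 0))
  structure(list(preset = preset, z_terms = z_terms, radial = radial),
            class = "groove_potential")
}

#' @export
print.groove_potential <- function(x, ...) {
  cat(sprintf("<groove_potential> preset '%s': %d Gaussian z-term(s), k_r in [%.2f, %.2f] kcal/mol/A^2\n",
              x$preset, nrow(x$z_terms), x$radial$base_k,
              x$radial$base_k + abs(x$radial$delta_k)))
  invisible(x)
}

#' In-plane confinement stiffness profile
#' @param potential a [groove_potential()].
#' @param z vector of z values, A.
#' @return k_r(z), kcal/mol/A^2.
#' @export
radial_k <- function(potential, z) {
  r <- potential$radial
  r$base_k + r$delta_k * exp(-(z - r$center)^2 / (2 * r$width^2))
}

.uz <- function(potential, z) {
  t <- potential$z_terms
  u <- numeric(length(z))
  for (i in seq_len(nrow(t))) {
    u <- u + t$amplitude[i] * exp(-(z - t$center[i])^2 / (2 * t$width[i]^2))
  }
  u
}

.duz <- function(potential, z) {
  t <- potential$z_terms
  g <- numeric(length(z))
  for (i in seq_len(nrow(t))) {
    g <- g - t$amplitude[i] * (z - t$center[i]) / t$width[i]^2 *
      exp(-(z - t$center[i])^2 / (2 * t$width[i]^2))
  }
  g
}

.dradial_k <- function(potential, z) {
  r <- potential$radial
  -r$delta_k * (z - r$center) / r$width^2 *
    exp(-(z - r$center)^2 / (2 * r$width^2))
}

#' Evaluate the 3-D groove potential
#' @param potential a [groove_potential()].
#' @param xyz numeric matrix (n x 3) or length-3 vector of positions, A.
#' @return potential energy, kcal/mol (length n).
#' @export
potential_energy <- function(potential, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  .uz(potential, xyz[, 3]) +
    0.5 * radial_k(potential, xyz[, 3]) * (xyz[, 1]^2 + xyz[, 2]^2)
}

#' Analytic gradient of the groove potential
#' @inheritParams potential_energy
#' @return n x 3 matrix of dU/dx, dU/dy, dU/dz, kcal/mol/A.
#' @export
potential_gradient <- function(potential, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  z <- xyz[, 3]
  kr <- radial_k(potential, z)
  rho2 <- xyz[, 1]^2 + xyz[, 2]^2
  cbind(kr * xyz[, 1],
        kr * xyz[, 2],
        .duz(potential, z) + 0.5 * .dradial_k(potential, z) * rho2)
}

#' Exact 1-D free-energy profile of a groove potential
#'
#' Analytic XY integration of the Boltzmann factor gives
#' `F(z) = U_z(z) + kT * log(k_r(z) / (2 pi kT))`.  This is the exact
#' ground truth against which WHAM recovery is judged.
#'
#' @inheritParams radial_k
#' @param temperature K.
#' @return F(z), kcal/mol (no offset convention applied).
#' @export
effective_pmf <- function(potential, z, temperature = .DEFAULT_TEMP) {
  kt <- kT(temperature)
  .uz(potential, z) + kt * log(radial_k(potential, z) / (2 * pi * kt))
}

#' Designed barrier of a preset (analytic)
#'
#' Max minus min of [effective_pmf()] over a z range, evaluated on a fine
#' grid of the exact profile.
#'
#' @inheritParams effective_pmf
#' @param z_range length-2 numeric, A.
#' @return barrier height, kcal/mol.
#' @export
designed_barrier <- function(potential, z_range, temperature = .DEFAULT_TEMP) {
  z <- seq(z_range[1], z_range[2], by = 0.01)
  f <- effective_pmf(potential, z, temperature)
  max(f) - min(f)
}
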