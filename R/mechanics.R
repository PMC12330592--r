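#' Mechanical layer of a laminate
#'
#' @param name Layer name.
#' @param youngs_modulus Young's modulus `E`, megapascals (> 0).
#' @param thickness Thickness, micrometers (> 0).
#' @param poisson_ratio Poisson ratio `nu` in [0, 0.5).
#' @return An object of class `mech_layer`.
#' @export
mech_layer <- function(name, youngs_modulus, thickness, poisson_ratio = 0.4) {
  stopifnot(youngs_modulus > 0, thickness > 0,
            poisson_ratio >= 0, poisson_ratio < 0.5)
  structure(list(name = name, e_mpa = youngs_modulus,
                 thickness_um = thickness, nu = poisson_ratio),
            class = "mech_layer")
}

#' Uniform pressure load on a clamped circular membrane
#'
#' @param radius Membrane radius, millimeters (> 0).
#' @param pressure Uniform pressure, pascals (>= 0). Cerebrospinal-fluid
#'   pressures span roughly 1-10 mmHg (133.32-1333.2 Pa).
#' @return An object of class `membrane_load` (edge condition: clamped).
#' @export
membrane_load <- function(radius, pressure) {
  stopifnot(radius > 0, pressure >= 0)
  structure(list(radius_mm = radius, pressure_pa = pressure,
                 edge_condition = "clamped"),
            class = "membrane_load")
}

#' Thickness-weighted (Voigt) effective elastic modulus
#'
#' `E_eff = sum(E_i t_i) / sum(t_i)`. For a 250 um PDMS (2 MPa) + 10 um
#' Parylene C (2.8 GPa) laminate this gives 109.62 MPa, in the range of
#' native dura tissue.
#'
#' @param layers List of [mech_layer()] objects.
#' @return Effective modulus, MPa.
#' @examples
#' pdms <- mech_layer("PDMS", 2, 250, 0.49)
#' pary <- mech_layer("Parylene C", 2800, 10, 0.40)
#' effective_modulus(list(pdms, pary))   # 109.62
#' @export
effective_modulus <- function(layers) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, logical(1), "mech_layer")))
  e <- vapply(layers, `[[`, numeric(1), "e_mpa")
  t <- vapply(layers, `[[`, numeric(1), "thickness_um")
  if (sum(t) <= 0) stop("zero total thickness")
  sum(e * t) / sum(t)
}

#' Composite-plate flexural rigidity
#'
#' Bending stiffness `D` of the laminate about its own neutral axis,
#' computed by the transformed-section method with plane-strain weighting
#' `E_i / (1 - nu_i^2)`:
#' `z_n = sum(E'_i t_i z_mid_i) / sum(E'_i t_i)` and
#' `D = sum(E'_i ((z_top_i - z_n)^3 - (z_bot_i - z_n)^3) / 3)`.
#' A single layer reduces to the classic `E t^3 / (12 (1 - nu^2))`.
#'
#' @param layers List of [mech_layer()] objects, ordered bottom to top.
#' @return Flexural rigidity, N m.
#' @export
flexural_rigidity <- function(layers) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, logical(1), "mech_layer")))
  e <- vapply(layers, `[[`, numeric(1), "e_mpa") * 1e6           # Pa
  t <- vapply(layers, `[[`, numeric(1), "thickness_um") * 1e-6   # m
  nu <- vapply(layers, `[[`, numeric(1), "nu")
  ep <- e / (1 - nu^2)
  z_top <- cumsum(t)
  z_bot <- z_top - t
  z_mid <- (z_top + z_bot) / 2
  zn <- sum(ep * t * z_mid) / sum(ep * t)
  sum(ep * ((z_top - zn)^3 - (z_bot - zn)^3) / 3)
}

#' Center deflection of a pressure-loaded clamped circular laminate
#'
#' Small-deflection plate bending plus the cubic membrane-stretching term
#' (Foeppl-type interpolation for a clamped plate with an immovable edge):
#' `P R^4 / (64 D) = w0 (1 + k (w0 / t)^2)`, solved for the positive root
#' `w0`. The stretching coefficient defaults to `k = 0.488` (the classical
#' clamped-edge value); in the small-pressure limit the solution converges
#' to the pure-bending `w0 = P R^4 / (64 D)`.
#'
#' @param layers List of [mech_layer()] objects.
#' @param load A [membrane_load()].
#' @param stretching_coefficient Dimensionless cubic coefficient `k`.
#' @return Center deflection, millimeters.
#' @examples
#' pdms <- mech_layer("PDMS", 2, 250, 0.49)
#' pary <- mech_layer("Parylene C", 2800, 10, 0.40)
#' membrane_deflection(list(pdms, pary), membrane_load(10, 600))
#' @export
membrane_deflection <- function(layers, load, stretching_coefficient = 0.488) {
  stopifnot(inherits(load, "membrane_load"))
  if (load$pressure_pa == 0) return(0)
  d <- flexural_rigidity(layers)
  r <- load$radius_mm * 1e-3
  t <- sum(vapply(layers, `[[`, numeric(1), "thickness_um")) * 1e-6
  rhs <- load$pressure_pa * r^4 / (64 * d)   # meters
  k <- stretching_coefficient
  # monotone cubic w + (k/t^2) w^3 = rhs; Cardano via polyroot fallback uniroot
  f <- function(w) w + k * w^3 / t^2 - rhs
  hi <- max(rhs, t)
  while (f(hi) < 0) hi <- hi * 2
  w0 <- stats::uniroot(f, c(0, hi), tol = 1e-15)$root
  if (w0 < 0) stop("no positive root")
  w0 * 1e3
}
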