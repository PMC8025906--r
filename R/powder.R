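# Particle- and bulk-level powder descriptors for carrier screening.
# All operations are deterministic pure functions; SI units internally,
# conventional reporting units (um, N/mm^2, m^2/g) at the interface.

#' Kelvin radius of capillary condensation
#'
#' Radius of the meniscus at which nitrogen condenses at relative pressure
#' `p_rel`, from the Kelvin relation in its magnitude convention
#' r_k = 2 sigma V / (R T ln(p0/p)), so that radii are positive for p/p0 < 1.
#' The pore radius is the Kelvin radius plus the adsorbed-layer thickness,
#' which the caller supplies (the instrument's proprietary layer-thickness
#' reduction is not reproduced here).
#'
#' @param p_rel Relative pressure p/p0, in (0, 1).
#' @param sigma Surface tension of liquid nitrogen (N/m), default 8.85e-3.
#' @param Vm Molar volume of liquid nitrogen (m^3/mol), default 34.7e-6.
#' @param T Absolute temperature (K), default 77.35.
#' @param t_layer Adsorbed-layer thickness (m), added to r_k; default 0.
#' @return Radius in metres.
#' @export
kelvin_radius <- function(p_rel, sigma = 8.85e-3, Vm = 34.7e-6, T = 77.35,
                          t_layer = 0) {
  if (any(p_rel <= 0 | p_rel >= 1))
    stop("`p_rel` must lie strictly in (0, 1); the radius diverges as p/p0 -> 1")
  stopifnot(sigma > 0, Vm > 0, T > 0)
  R <- 8.314462618  # universal gas constant, J/(mol K)
  2 * sigma * Vm / (R * T * log(1 / p_rel)) + t_layer
}

#' Heywood equivalent diameter
#'
#' de = sqrt(3.08 W L / pi) from the particle width and length (maximum and
#' minimum Ferret diameters from image analysis).
#'
#' @param W,L Particle width and length (same length unit; returned unit
#'   matches).
#' @return Heywood diameter.
#' @export
heywood_diameter <- function(W, L) {
  stopifnot(all(W > 0), all(L > 0))
  sqrt(3.08 * W * L / pi)
}

#' Shape coefficient of a particle population
#'
#' alpha = SSA * rho_s * de + N, with N the elongation ratio L/W. The additive
#' form is used as printed in the source formula; `variant = "multiplicative"`
#' evaluates the alternative reading alpha = SSA * rho_s * de * N.
#'
#' @param SSA Specific surface area (m^2/kg).
#' @param rho_s Particle true density (kg/m^3).
#' @param de Heywood diameter (m).
#' @param N Elongation ratio L/W (>= 1).
#' @param variant `"additive"` (default) or `"multiplicative"`.
#' @return Dimensionless shape coefficient.
#' @export
shape_coefficient <- function(SSA, rho_s, de, N,
                              variant = c("additive", "multiplicative")) {
  variant <- match.arg(variant)
  stopifnot(SSA > 0, rho_s > 0, de > 0, N >= 1)
  if (variant == "additive") SSA * rho_s * de + N else SSA * rho_s * de * N
}

#' Tensile strength of a powder compact
#'
#' Diametral-compression strength TS = 2P / (pi D t).
#'
#' @param P Crushing load (N).
#' @param D Compact diameter (mm).
#' @param t Compact thickness (mm).
#' @return Tensile strength in N/mm^2.
#' @export
tensile_strength <- function(P, D, t) {
  stopifnot(all(P >= 0), all(D > 0), all(t > 0))
  2 * P / (pi * D * t)
}

#' Mean and endpoint-difference summary of a rheology profile
#'
#' For a profile of responses measured at increasing applied normal stresses
#' (incipient shear stress, compressibility or pressure drop), returns the
#' arithmetic mean of the values at stresses within `[lo, hi]` (the sigma
#' descriptor) and the absolute difference between the values at exactly `hi`
#' and `lo` (the delta descriptor).
#'
#' @param levels Applied normal stresses (kPa), strictly increasing.
#' @param values Measured responses, same length as `levels`.
#' @param lo,hi Summary window endpoints; both must be present in `levels`.
#' @return List with `sigma_mean` and `delta_abs`.
#' @export
rheology_summary <- function(levels, values, lo, hi) {
  stopifnot(length(levels) == length(values), all(diff(levels) > 0))
  i_lo <- match(lo, levels)
  i_hi <- match(hi, levels)
  if (is.na(i_lo) || is.na(i_hi))
    stop("missing level: `lo` and `hi` must both be present among `levels`")
  inside <- levels >= lo & levels <= hi
  list(sigma_mean = mean(values[inside]),
       delta_abs = abs(values[i_hi] - values[i_lo]))
}

#' Pressure-titration de-agglomeration deltas
#'
#' Change of the 10th size percentile (Dv0.1) and of the fines fraction
#' (< 10 um, %) between the lowest measured primary dispersion pressure
#' (the baseline) and `to_pdp`. Both deltas are signed so that
#' de-agglomeration (Dv0.1 falling, fines rising) is positive.
#'
#' @param pdp Primary dispersion pressures (bar), strictly increasing.
#' @param dv01 Dv0.1 values (um), same length as `pdp`.
#' @param fines Fines fractions (%), same length as `pdp`.
#' @param to_pdp Target pressure; must be present in `pdp`.
#' @return List with `delta_dv01` (um) and `delta_fines` (%).
#' @export
titration_deltas <- function(pdp, dv01, fines, to_pdp) {
  stopifnot(length(pdp) == length(dv01), length(pdp) == length(fines),
            all(diff(pdp) > 0))
  i <- match(to_pdp, pdp)
  if (is.na(i)) stop("missing level: `to_pdp` not among measured pressures")
  list(delta_dv01 = dv01[1L] - dv01[i],
       delta_fines = fines[i] - fines[1L])
}
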