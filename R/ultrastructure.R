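#' Axo-myelin ultrastructure algebra
#'
#' Closed-form relations linking the passive cable parameters of a myelinated
#' axon to its ultrastructure: the periaxonal space geometry, the number of
#' compacted myelin lamellae, the radial thickness of the sheath, and the
#' g-ratio. All functions are pure, vectorised over their numeric arguments,
#' and reject non-positive inputs.
#'
#' Unit conventions follow the fields of [cable_params()]: resistivities in
#' ohm cm, specific membrane resistances in kilo-ohm cm^2, specific
#' capacitances in uF/cm^2, per-length axial resistances in ohm/cm, diameters
#' in um and widths in nm.
#'
#' @name ultrastructure
NULL

# module constants (overridable wherever they appear as defaults)
DELTA_M_NM  <- 8    # single membrane thickness incl. proteins, nm
DELTA_PN_NM <- 7.4  # paranodal gap width, nm

#' Axial resistance of the axon core
#'
#' Per-length axial resistance of a cylindrical axon core,
#' `r_i = 4 R_i / (pi d^2)`.
#'
#' @param R_i axoplasmic resistivity, ohm cm.
#' @param d axon core diameter, um.
#' @return Axial resistance in ohm/cm.
#' @examples
#' core_axial_resistance(100, 1) # ~1.27e10 ohm/cm for a 1 um axon
#' @export
core_axial_resistance <- function(R_i, d) {
  check_positive(R_i = R_i, d = d)
  4 * R_i / (pi * (d / UM_PER_CM)^2)
}

#' Periaxonal fluid resistivity from per-length axial resistance
#'
#' Converts the per-length axial resistance of the periaxonal space into a
#' fluid resistivity using the annular cross-section between axolemma and
#' inner myelin: `R_pa = r_pa * pi * delta_pa * (d + delta_pa)`.
#'
#' @param r_pa periaxonal axial resistance, ohm/cm.
#' @param d axon core diameter, um.
#' @param delta_pa periaxonal width, nm.
#' @return Resistivity in ohm cm.
#' @examples
#' # mean optimized periaxonal resistance and EM-measured width give a
#' # resistivity close to that of cortical extracellular fluid
#' periaxonal_resistivity(125e9, d = 1.1, delta_pa = 12.3)
#' @export
periaxonal_resistivity <- function(r_pa, d, delta_pa) {
  check_positive(r_pa = r_pa, d = d, delta_pa = delta_pa)
  d_cm <- d / UM_PER_CM
  dpa_cm <- delta_pa / NM_PER_CM
  r_pa * pi * dpa_cm * (d_cm + dpa_cm)
}

#' Periaxonal width from axial resistance and fluid resistivity
#'
#' Inverts [periaxonal_resistivity()] for the width of the annulus:
#' `delta_pa = (-d + sqrt(d^2 + 4 R_pa / (pi r_pa))) / 2`.
#'
#' @inheritParams periaxonal_resistivity
#' @param R_pa periaxonal fluid resistivity, ohm cm.
#' @return Width in nm.
#' @export
periaxonal_width <- function(r_pa, d, R_pa) {
  check_positive(r_pa = r_pa, d = d, R_pa = R_pa)
  d_cm <- d / UM_PER_CM
  dpa_cm <- 0.5 * (-d_cm + sqrt(d_cm^2 + 4 * R_pa / (pi * r_pa)))
  dpa_cm * NM_PER_CM
}

#' Number of myelin lamellae from sheath capacitance
#'
#' A compact sheath of `n_my` lamellae (two membranes each) behaves as
#' `2 n_my` identical capacitors in series, so when the single myelin
#' membrane has the same specific capacitance as the axolemma,
#' `n_my = C_m / (2 C_my)`.
#'
#' @param C_m axolemma specific capacitance, uF/cm^2.
#' @param C_my whole-sheath radial specific capacitance, uF/cm^2.
#' @return Lamella count (continuous; round only for reporting).
#' @examples
#' lamellae_from_sheath(C_m = 1, C_my = 0.05) # 10 lamellae
#' @export
lamellae_from_sheath <- function(C_m, C_my) {
  check_positive(C_m = C_m, C_my = C_my)
  if (any(C_my >= C_m)) {
    abort("`C_my` must be smaller than `C_m`: a sheath of >= 1 lamella has less capacitance than one membrane")
  }
  C_m / (2 * C_my)
}

#' Sheath radial properties from single-membrane properties
#'
#' Series compaction of `2 n_my` identical membranes:
#' `R_my = 2 n_my R_mm` and `C_my = C_mm / (2 n_my)`.
#'
#' @param R_mm single myelin membrane specific resistance, kOhm cm^2.
#' @param C_mm single myelin membrane specific capacitance, uF/cm^2.
#' @param n_my number of lamellae.
#' @return A tibble with columns `R_my` (kOhm cm^2) and `C_my` (uF/cm^2).
#' @export
sheath_from_lamellae <- function(R_mm, C_mm, n_my) {
  check_positive(R_mm = R_mm, C_mm = C_mm, n_my = n_my)
  tibble(R_my = 2 * n_my * R_mm, C_my = C_mm / (2 * n_my))
}

#' Single-membrane properties from sheath properties
#'
#' Inverse of [sheath_from_lamellae()]: `R_mm = R_my / (2 n_my)`,
#' `C_mm = 2 n_my C_my`.
#'
#' @param R_my whole-sheath radial specific resistance, kOhm cm^2.
#' @param C_my whole-sheath radial specific capacitance, uF/cm^2.
#' @param n_my number of lamellae (e.g. the EM-measured mean).
#' @return A tibble with columns `R_mm` (kOhm cm^2) and `C_mm` (uF/cm^2).
#' @export
membrane_props_from_sheath <- function(R_my, C_my, n_my) {
  check_positive(R_my = R_my, C_my = C_my, n_my = n_my)
  tibble(R_mm = R_my / (2 * n_my), C_mm = 2 * n_my * C_my)
}

#' Radial thickness of the myelin sheath
#'
#' Treating each membrane as a slice of the sheath capacitor with a shared
#' dielectric constant gives `delta_m * C_m = delta_my * C_my`, so
#' `delta_my = delta_m * C_m / C_my`.
#'
#' @inheritParams lamellae_from_sheath
#' @param delta_m single membrane thickness, nm (default 8).
#' @return Sheath thickness in nm.
#' @export
sheath_thickness <- function(C_m, C_my, delta_m = DELTA_M_NM) {
  check_positive(C_m = C_m, C_my = C_my, delta_m = delta_m)
  delta_m * C_m / C_my
}

#' g-ratio
#'
#' Ratio of inner (axon core) to outer (fiber) diameter.
#'
#' @param d axon core diameter, um.
#' @param D outer fiber diameter, um.
#' @return Dimensionless ratio in (0, 1).
#' @export
g_ratio <- function(d, D) {
  check_positive(d = d, D = D)
  if (any(d >= D)) abort("`d` must be smaller than `D`")
  d / D
}

#' Optical resolving distance
#'
#' Rayleigh-type resolving distance of a brightfield setup,
#' `rd = 1.22 lambda / (NA_obj + NA_cond)`; used to size the random
#' perturbation applied to reconstructed internodal diameters.
#'
#' @param lambda_nm wavelength, nm.
#' @param NA_obj objective numerical aperture.
#' @param NA_cond condenser numerical aperture.
#' @return Resolving distance in nm.
#' @examples
#' resolving_distance(550, 1.4, 0.9) # ~292 nm, i.e. ~300 nm
#' @export
resolving_distance <- function(lambda_nm, NA_obj, NA_cond) {
  check_positive(lambda_nm = lambda_nm, NA_obj = NA_obj, NA_cond = NA_cond)
  1.22 * lambda_nm / (NA_obj + NA_cond)
}
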