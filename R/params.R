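#' Passive cable parameter set
#'
#' The full passive parameter vector of the double-cable circuit. Units are
#' fixed per field and all internal conversions are handled by the solver.
#'
#' @param R_i axoplasmic resistivity, ohm cm.
#' @param R_m axolemma specific membrane resistance, kOhm cm^2.
#' @param C_m axolemma specific membrane capacitance, uF/cm^2.
#' @param R_my whole-sheath radial specific resistance, kOhm cm^2
#'   (referred to the axolemma area).
#' @param C_my whole-sheath radial specific capacitance, uF/cm^2.
#' @param r_pa periaxonal axial resistance per length, ohm/cm.
#' @param r_pn paranodal axial resistance per length, ohm/cm.
#' @param C_pip residual pipette wall capacitance, uF/cm^2 of modelled
#'   pipette surface (only used when a pipette is attached).
#' @return An object of class `cable_params` (named list).
#' @examples
#' p <- cable_params()
#' p$R_my / p$R_m
#' @export
cable_params <- function(R_i = 100, R_m = 15, C_m = 1,
                         R_my = 205, C_my = 1 / 24,
                         r_pa = 125e9, r_pn = 2.45e12,
                         C_pip = 5.5e-5) {
  check_positive(R_i = R_i, R_m = R_m, C_m = C_m, R_my = R_my,
                 C_my = C_my, r_pa = r_pa, r_pn = r_pn, C_pip = C_pip)
  structure(list(R_i = R_i, R_m = R_m, C_m = C_m, R_my = R_my, C_my = C_my,
                 r_pa = r_pa, r_pn = r_pn, C_pip = C_pip),
            class = "cable_params")
}

#' @export
print.cable_params <- function(x, ...) {
  cat("<cable_params>\n")
  units <- c(R_i = "ohm cm", R_m = "kOhm cm2", C_m = "uF/cm2",
             R_my = "kOhm cm2", C_my = "uF/cm2", r_pa = "ohm/cm",
             r_pn = "ohm/cm", C_pip = "uF/cm2")
  for (nm in names(units)) {
    cat(sprintf("  %-6s %12.5g %s\n", nm, x[[nm]], units[[nm]]))
  }
  invisible(x)
}

#' @export
as_tibble.cable_params <- function(x, ...) {
  tibble(parameter = names(unclass(x)), value = unlist(unclass(x), use.names = FALSE))
}

#' Default parameter bounds for fitting
#'
#' Box bounds per parameter, derived from ultrastructural expectations:
#' the sheath resistance brackets 10-100 lamellae of a single-membrane
#' resistance between literature extremes, the sheath capacitance brackets
#' the axolemma bounds folded through 10-100 lamellae, the lower periaxonal
#' axial bound corresponds to a 35 ohm cm fluid (squid axoplasm) in a wide
#' 300 nm space around a thin 0.5 um axon, and the upper bound to deionised
#' water (2 MOhm cm) in a 1 nm space (the Debye-limited minimum) around a
#' thick 2 um axon. The paranodal upper bound is 100x the periaxonal one.
#'
#' All parameters are searched on a log scale.
#'
#' @param R_mm_range single myelin membrane resistance extremes, kOhm cm^2.
#' @param C_m_range axolemma capacitance extremes, uF/cm^2.
#' @return A tibble with columns `parameter`, `low`, `high`, `transform`,
#'   `fit`.
#' @export
default_bounds <- function(R_mm_range = c(1.8, 16), C_m_range = c(0.5, 2)) {
  r_pa_low  <- periaxonal_resistivity_inverse(35, d = 0.5, delta_pa = 300)
  r_pa_high <- periaxonal_resistivity_inverse(2e6, d = 2, delta_pa = 1)
  tibble(
    parameter = c("R_i", "R_m", "C_m", "R_my", "C_my", "r_pa", "r_pn", "C_pip"),
    low  = c(50, 1, C_m_range[1],
             2 * 10 * R_mm_range[1], C_m_range[1] / (2 * 100),
             r_pa_low, r_pa_low, 1e-7),
    high = c(400, 100, C_m_range[2],
             2 * 100 * R_mm_range[2], C_m_range[2] / (2 * 10),
             r_pa_high, 100 * r_pa_high, 1.29e-4),
    transform = "log",
    fit = TRUE
  )
}

# r_pa from a target resistivity, width and diameter (Eq 5 solved for r_pa)
periaxonal_resistivity_inverse <- function(R_pa, d, delta_pa) {
  d_cm <- d / UM_PER_CM
  dpa_cm <- delta_pa / NM_PER_CM
  R_pa / (pi * dpa_cm * (d_cm + dpa_cm))
}

params_in_bounds <- function(params, bounds) {
  p <- unlist(unclass(params))[bounds$parameter]
  all(p >= bounds$low & p <= bounds$high)
}
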