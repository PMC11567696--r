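#' Concentration conversions
#'
#' Convert molar concentration to number density and back. Internally the
#' package works in number densities (1/m^3) so that the rate equations take
#' the form printed in the adsorption-kinetics literature (e.g. the
#' Smoluchowski rate 4*pi*r0*C*D in 1/s with C in 1/m^3).
#'
#' @param c Molar concentration, mol/L. Vectorized, must be >= 0.
#' @param C Number density, 1/m^3. Vectorized, must be >= 0.
#'
#' @return `molar_to_number_density` returns 1/m^3; `number_density_to_molar`
#'   returns mol/L. The pair is an exact inverse (linear maps).
#'
#' @examples
#' molar_to_number_density(1e-9)          # 1 nM -> 6.022e17 /m^3
#' number_density_to_molar(6.02214076e26) # 1 mol/L
#' @export
molar_to_number_density <- function(c) {
  .check_pos(c, "c", zero_ok = TRUE)
  c * 1000 * AVOGADRO
}

#' @rdname molar_to_number_density
#' @export
number_density_to_molar <- function(C) {
  .check_pos(C, "C", zero_ok = TRUE)
  C / (1000 * AVOGADRO)
}

#' @rdname molar_to_number_density
#' @param c_nM Concentration in nanomolar.
#' @export
nM_to_number_density <- function(c_nM) molar_to_number_density(c_nM * 1e-9)

#' @rdname molar_to_number_density
#' @export
number_density_to_nM <- function(C) number_density_to_molar(C) * 1e9
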