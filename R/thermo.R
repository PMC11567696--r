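#' Arrhenius pseudo-first-order rate
#'
#' k = F_BA * exp(-Ea / (R*T)): the per-target collision-attempt frequency
#' F_BA attenuated by the Boltzmann factor of the molar activation energy.
#' A barrierless reaction (Ea = 0) proceeds at the attempt frequency.
#'
#' @param F_BA Attempt (collision) frequency, 1/s, >= 0.
#' @param Ea Molar activation energy, J/mol (may be negative).
#' @param T Temperature, K.
#' @return Rate, 1/s.
#' @export
arrhenius_pseudo_first_order <- function(F_BA, Ea, T) {
  .check_pos(F_BA, "F_BA", zero_ok = TRUE)
  if (!is.numeric(Ea) || any(!is.finite(Ea))) {
    stop("`Ea` must be finite numeric", call. = FALSE)
  }
  .check_pos(T, "T")
  F_BA * exp(-Ea / (GAS_CONSTANT * T))
}

#' Equilibrium constant from reaction free energy
#'
#' Ka = exp(-dG / (R*T)) / C_ref, with the reference concentration C_ref
#' (default 1 mol/L = 1000 mol/m^3) making Ka dimensional (L/mol when
#' C_ref is in mol/L equivalents). The companion identities
#' Ka = kf/kb = 1/Kd hold by definition.
#'
#' @param dG Reaction free energy, J/mol.
#' @param T Temperature, K.
#' @param C_ref Reference concentration, mol/m^3 (default 1000 = 1 mol/L).
#' @return Ka in 1/(mol/m^3) scaled such that Ka * C_ref is the
#'   dimensionless equilibrium ratio.
#' @export
equilibrium_constant_from_free_energy <- function(dG, T, C_ref = 1000) {
  if (!is.numeric(dG) || any(!is.finite(dG))) {
    stop("`dG` must be finite numeric", call. = FALSE)
  }
  .check_pos(T, "T"); .check_pos(C_ref, "C_ref")
  exp(-dG / (GAS_CONSTANT * T)) / C_ref
}
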