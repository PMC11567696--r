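#' Stokes-Einstein diffusion coefficient
#'
#' D = kB*T / (6*pi*eta*r0) for a sphere of radius r0 in a solvent of
#' viscosity eta at temperature T.
#'
#' @param temperature K.
#' @param viscosity Pa s.
#' @param radius Hydrodynamic radius, m.
#' @return Diffusion coefficient, m^2/s.
#' @examples
#' stokes_einstein_D(298, 8.9e-4, 0.9e-9)  # ~2.7e-10 m^2/s, a small dye
#' @export
stokes_einstein_D <- function(temperature, viscosity, radius) {
  .check_pos(temperature, "temperature")
  .check_pos(viscosity, "viscosity")
  .check_pos(radius, "radius")
  BOLTZMANN * temperature / (6 * pi * viscosity * radius)
}

#' Molecular radius from molecular weight
#'
#' Inverts Mw = (4/3)*pi*NA*r0^3*rho, i.e. treats the molecule as a sphere
#' of the neat material's density.
#'
#' @param Mw Molecular weight, kg/mol.
#' @param density Neat density, kg/m^3.
#' @return Radius, m.
#' @examples
#' radius_from_molweight(1.271, 1000)  # ~0.8 nm for a 1271 g/mol dye
#' @export
radius_from_molweight <- function(Mw, density) {
  .check_pos(Mw, "Mw")
  .check_pos(density, "density")
  (3 * Mw / (4 * pi * AVOGADRO * density))^(1 / 3)
}

#' Relative diffusion coefficient
#'
#' When both partners diffuse the encounter kinetics are governed by
#' D = D_a + D_b; an immobilized target contributes 0.
#'
#' @param D_a,D_b Diffusion coefficients, m^2/s, >= 0.
#' @return m^2/s.
#' @export
relative_diffusion <- function(D_a, D_b) {
  .check_pos(D_a, "D_a", zero_ok = TRUE)
  .check_pos(D_b, "D_b", zero_ok = TRUE)
  D_a + D_b
}

#' Mean molecular separation
#'
#' L = C^(-1/3), the average nearest-neighbor distance in a dilute solution
#' of number density C. `C = 0` returns `Inf` (empty solution) rather than
#' erroring, so dataset-level code can pass blank rows through.
#'
#' @param C Number density, 1/m^3, >= 0.
#' @return Separation, m.
#' @examples
#' mean_separation(nM_to_number_density(1))  # ~1.2 micrometers at 1 nM
#' @export
mean_separation <- function(C) {
  .check_pos(C, "C", zero_ok = TRUE)
  ifelse(C == 0, Inf, C^(-1 / 3))
}

#' Critical (nearest-neighbor reshuffle) time
#'
#' The time at which the root-mean-square diffusive displacement
#' sqrt(2*D*t) equals the mean separation L = C^(-1/3):
#' t_c = 1 / (2*D*C^(2/3)). In the discrete adsorption models the virtual
#' concentration gradient restarts every t_c because the target cannot
#' distinguish one nearest neighbor from the next.
#'
#' `fractal_correction` halves t_c, the empirical factor ~2 bridging
#' continuous diffusion with the discrete per-t_c counting (self-similar
#' sub-steps). It is off by default: the rate equations that use the factor
#' carry it explicitly in their own coefficients, so double counting is
#' impossible.
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param C Number density, 1/m^3 (0 gives `Inf`).
#' @param fractal_correction Logical; halve the reshuffle time.
#' @return Time, s.
#' @examples
#' critical_time(2.9e-10, nM_to_number_density(1))  # ~2.4 ms
#' @export
critical_time <- function(D, C, fractal_correction = FALSE) {
  .check_pos(D, "D")
  .check_pos(C, "C", zero_ok = TRUE)
  tc <- ifelse(C == 0, Inf, 1 / (2 * D * C^(2 / 3)))
  if (isTRUE(fractal_correction)) tc <- tc / 2
  tc
}

#' 3D Gaussian diffusion propagator
#'
#' Probability density (1/m^3) of finding a molecule released at the origin
#' at distance R after time t of free diffusion:
#' p = (4*pi*D*t)^(-3/2) * exp(-R^2 / (4*D*t)).
#' `propagator_radial` returns the radial density 4*pi*R^2*p (1/m), which
#' integrates to 1 over R in (0, Inf) and peaks at R* = 2*sqrt(D*t).
#'
#' @param elapsed_time s, > 0.
#' @param diffusion_coefficient m^2/s, > 0.
#' @param radius_from_origin m, >= 0. Vectorized.
#' @return Density: 1/m^3 (`propagator_pdf`) or 1/m (`propagator_radial`).
#' @examples
#' # radial density peaks at 2*sqrt(D*t)
#' propagator_radial(1, 1e-10, 2 * sqrt(1e-10))
#' @export
propagator_pdf <- function(elapsed_time, diffusion_coefficient,
                           radius_from_origin) {
  .check_pos(elapsed_time, "elapsed_time")
  .check_pos(diffusion_coefficient, "diffusion_coefficient")
  .check_pos(radius_from_origin, "radius_from_origin", zero_ok = TRUE)
  s2 <- 4 * diffusion_coefficient * elapsed_time
  (pi * s2)^(-3 / 2) * exp(-radius_from_origin^2 / s2)
}

#' @rdname propagator_pdf
#' @export
propagator_radial <- function(elapsed_time, diffusion_coefficient,
                              radius_from_origin) {
  4 * pi * radius_from_origin^2 *
    propagator_pdf(elapsed_time, diffusion_coefficient, radius_from_origin)
}

#' 1D first-passage probability
#'
#' Probability that a 1D Brownian walker started at the origin has reached
#' the level L at least once by time t: erfc(L / sqrt(4*D*t)) (reflection
#' principle). Closed-form oracle for the Monte Carlo module.
#'
#' @param L Distance, m, > 0.
#' @param D m^2/s, > 0.
#' @param t s, > 0.
#' @return Probability in (0, 1).
#' @export
first_passage_prob_1d <- function(L, D, t) {
  .check_pos(L, "L"); .check_pos(D, "D"); .check_pos(t, "t")
  erfc(L / sqrt(4 * D * t))
}

#' Hard-sphere collision frequency
#'
#' Number of collisions per second of one molecule A with partners B at
#' number density C_B, cross section sigma, reduced mass m, temperature T:
#' F = sigma * C_B * <v> with the Maxwell-Boltzmann mean relative speed
#' <v> = sqrt(8*kB*T / (pi*m)). This is the closed form of the
#' speed-distribution integral over all collision angles.
#'
#' @param cross_section m^2.
#' @param reduced_mass kg.
#' @param temperature K.
#' @param partner_concentration 1/m^3.
#' @return Collision frequency, 1/s.
#' @export
collision_frequency_hard_sphere <- function(cross_section, reduced_mass,
                                            temperature,
                                            partner_concentration) {
  .check_pos(cross_section, "cross_section")
  .check_pos(reduced_mass, "reduced_mass")
  .check_pos(temperature, "temperature")
  .check_pos(partner_concentration, "partner_concentration")
  v_mean <- sqrt(8 * BOLTZMANN * temperature / (pi * reduced_mass))
  cross_section * partner_concentration * v_mean
}
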