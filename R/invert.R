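#' Invert a rate model for its geometry parameter
#'
#' Each time-independent model is linear in its single geometry parameter,
#' so the inversion from a measured per-target rate is closed-form:
#' \itemize{
#'   \item `discrete_0d`: a = r / (4*D*C^(2/3))
#'   \item `smoluchowski_1d`: r0 = r / (4*pi*C*D)
#'   \item `discrete_2d`: A = r*pi / (4*D*C^(4/3))
#'   \item `discrete_2d_tc`: A = r / (2*sqrt(2/pi)*D*C^(4/3))
#'   \item `discrete_3d`: V0 = r / (4*D*C^(5/3))
#' }
#' The time-dependent models are excluded here; use
#' [invert_langmuir_schaefer()] with an explicit time.
#'
#' @param model Model id or alias (time-independent models only).
#' @param r Measured rate, 1/s, >= 0.
#' @param C Number density, 1/m^3.
#' @param D Diffusion coefficient, m^2/s.
#' @return Named numeric: the geometry parameter in SI, named by its symbol
#'   (`a`, `r0`, `A` or `V0`).
#' @examples
#' invert_model("smoluchowski", 0.63, nM_to_number_density(1), 2.9e-10)
#' # r0 ~ 0.29 nm
#' @export
invert_model <- function(model, r, C, D) {
  m <- .match_model(model)
  .check_pos(r, "r", zero_ok = TRUE)
  .check_pos(C, "C"); .check_pos(D, "D")
  reg <- model_registry()[[m]]
  if (reg$time_dependent) {
    stop(sprintf("model '%s' is time-dependent; use invert_langmuir_schaefer()",
                 m), call. = FALSE)
  }
  val <- r / (reg$coefficient * D * C^reg$concentration_exponent)
  stats::setNames(val, reg$geometry_symbol)
}

#' @rdname invert_model
#' @param t Elapsed time, s.
#' @export
invert_langmuir_schaefer <- function(r, C, D, t) {
  .check_pos(r, "r", zero_ok = TRUE)
  .check_pos(C, "C"); .check_pos(D, "D"); .check_pos(t, "t")
  stats::setNames(r / (2 * C * sqrt(D / (pi * t))), "A")
}

#' Cylinder conventions for effective radii
#'
#' For a cylindrical target of length `ell`, an inverted binding area maps
#' to an effective radius r0 = A/ell (rectangular footprint of width r0
#' along the cylinder) and an inverted collision volume to
#' r0 = sqrt(V0/ell) (square-cross-section prism of side r0). These
#' conventions reproduce the effective-radius columns of the worked
#' single-molecule DNA example; they are inferred reporting conventions,
#' not physical derivations.
#'
#' @param A Binding area, m^2.
#' @param V0 Collision volume, m^3.
#' @param ell Cylinder length, m (default 1 micrometer, a stretched
#'   lambda-DNA fragment).
#' @return Effective radius, m.
#' @examples
#' cylinder_radius_from_area(3.4e-15, 1e-6) * 1e9   # ~3.4 nm
#' cylinder_radius_from_volume(1.3e-21, 1e-6) * 1e9 # ~36 nm
#' @export
cylinder_radius_from_area <- function(A, ell = 1e-6) {
  .check_pos(A, "A"); .check_pos(ell, "ell")
  A / ell
}

#' @rdname cylinder_radius_from_area
#' @export
cylinder_radius_from_volume <- function(V0, ell = 1e-6) {
  .check_pos(V0, "V0"); .check_pos(ell, "ell")
  sqrt(V0 / ell)
}
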