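#' Model registry
#'
#' The model family, keyed by id. Each entry records the multiplicative
#' coefficient, the exponents of concentration, diffusion coefficient and
#' time, and the geometry parameter symbol. The registry is the single
#' source of truth for [dimensional_signature()], [predict_rate()] and
#' [invert_model()].
#'
#' Model ids:
#' \describe{
#'   \item{`naive_continuous`}{r = C*V0/t. The overlap-counting argument with
#'     a continuous clock; dimensionally correct but independent of D.}
#'   \item{`discrete_0d`}{r = 2a/t_c = 4*a*D*C^(2/3). Effective fraction a of
#'     nearest-neighbor attempts that hit, one attempt per reshuffle time,
#'     with the factor-2 fractal correction built into the printed
#'     coefficient.}
#'   \item{`smoluchowski_1d`}{r = 4*pi*r0*C*D. Steady-state diffusive flux
#'     onto an absorbing sphere of radius r0.}
#'   \item{`discrete_2d`}{r = (4/pi)*A*D*C^(4/3). The 0D model with
#'     a = 4A/(4*pi*L^2) (binding area over the first-neighbor sphere,
#'     four effective neighbors) and L = C^(-1/3).}
#'   \item{`discrete_2d_tc`}{r = 2*sqrt(2/pi)*A*D*C^(4/3). The
#'     Langmuir-Schaefer rate evaluated at t = t_c.}
#'   \item{`langmuir_schaefer`}{r = 2*A*C*sqrt(D/(pi*t)). Transient
#'     adsorption to an absorbing interface under an evolving Fick
#'     gradient.}
#'   \item{`discrete_3d`}{r = 2*C*V0/t_c = 4*V0*D*C^(5/3). Volume-overlap
#'     counting per reshuffle time; equals the 0D model with a = C*V0.}
#' }
#'
#' @return `model_ids()` returns the ids in canonical order;
#'   `model_registry()` the full registry as a named list.
#' @export
model_ids <- function() {
  c("naive_continuous", "discrete_0d", "smoluchowski_1d", "discrete_2d",
    "discrete_2d_tc", "langmuir_schaefer", "discrete_3d")
}

#' @rdname model_ids
#' @export
model_registry <- function() {
  list(
    naive_continuous = list(
      coefficient = 1, concentration_exponent = 1, diffusion_exponent = 0,
      time_exponent = -1, geometry_symbol = "V0", time_dependent = TRUE),
    discrete_0d = list(
      coefficient = 4, concentration_exponent = 2 / 3, diffusion_exponent = 1,
      time_exponent = 0, geometry_symbol = "a", time_dependent = FALSE),
    smoluchowski_1d = list(
      coefficient = 4 * pi, concentration_exponent = 1, diffusion_exponent = 1,
      time_exponent = 0, geometry_symbol = "r0", time_dependent = FALSE),
    discrete_2d = list(
      coefficient = 4 / pi, concentration_exponent = 4 / 3,
      diffusion_exponent = 1,
      time_exponent = 0, geometry_symbol = "A", time_dependent = FALSE),
    discrete_2d_tc = list(
      coefficient = 2 * sqrt(2 / pi), concentration_exponent = 4 / 3,
      diffusion_exponent = 1,
      time_exponent = 0, geometry_symbol = "A", time_dependent = FALSE),
    langmuir_schaefer = list(
      coefficient = 2 / sqrt(pi), concentration_exponent = 1,
      diffusion_exponent = 1 / 2,
      time_exponent = -1 / 2, geometry_symbol = "A", time_dependent = TRUE),
    discrete_3d = list(
      coefficient = 4, concentration_exponent = 5 / 3, diffusion_exponent = 1,
      time_exponent = 0, geometry_symbol = "V0", time_dependent = FALSE)
  )
}

.match_model <- function(model) {
  aliases <- c(naive = "naive_continuous", "0d" = "discrete_0d",
               smoluchowski = "smoluchowski_1d", "1d" = "smoluchowski_1d",
               "2d" = "discrete_2d", "2d_tc" = "discrete_2d_tc",
               ls = "langmuir_schaefer", "3d" = "discrete_3d")
  m <- tolower(model)
  if (m %in% names(aliases)) m <- unname(aliases[m])
  if (!m %in% model_ids()) {
    stop(sprintf("unknown model id '%s' (known: %s)", model,
                 paste(model_ids(), collapse = ", ")), call. = FALSE)
  }
  m
}

#' Naive continuous overlap rate
#'
#' r = C*V0/t: the collision-volume overlap of a continuously evolving
#' single-molecule propagator, counted against a continuous clock. Kept in
#' the family because its failure (no dependence on D, rate decaying as
#' 1/t) motivates the discrete reshuffle-time models.
#'
#' @param C Number density, 1/m^3.
#' @param V0 Collision volume, m^3.
#' @param t Elapsed time, s.
#' @return Rate, 1/s.
#' @export
rate_naive <- function(C, V0, t) {
  .check_pos(C, "C"); .check_pos(V0, "V0"); .check_pos(t, "t")
  C * V0 / t
}

#' Discrete 0D rate
#'
#' r = 2a/t_c = 4*a*D*C^(2/3): an effective fraction `a` of
#' nearest-neighbor encounter attempts hit the target, one attempt per
#' reshuffle time t_c, times the factor-2 fractal correction.
#'
#' @param a Effective fraction, dimensionless in \[0, 1\].
#' @param D Relative diffusion coefficient, m^2/s.
#' @param C Number density, 1/m^3.
#' @return Rate, 1/s.
#' @examples
#' rate_0d(0.87e-3, 2.9e-10, nM_to_number_density(3))  # ~1.5 /s
#' @export
rate_0d <- function(a, D, C) {
  .check_pos(a, "a", zero_ok = TRUE)
  if (any(a > 1)) stop("`a` must lie in [0, 1]", call. = FALSE)
  .check_pos(D, "D"); .check_pos(C, "C")
  4 * a * D * C^(2 / 3)
}

#' Effective fraction from binding area
#'
#' a = 4A/(4*pi*L^2) = A/(pi*L^2): the ratio of the target-probe binding
#' cross section to the surface of the first-neighbor sphere, with four
#' effective probes in the first neighbor shell (cubic/tetrahedral
#' packing).
#'
#' @param A Binding area, m^2.
#' @param L Nearest-neighbor distance, m.
#' @return Dimensionless fraction in (0, 1].
#' @export
effective_fraction_from_area <- function(A, L) {
  .check_pos(A, "A"); .check_pos(L, "L")
  a <- A / (pi * L^2)
  if (any(a > 1)) {
    stop("binding area exceeds the first-neighbor sphere (a > 1)",
         call. = FALSE)
  }
  a
}

#' Effective fraction from collision volume
#'
#' a = C*V0: the probe collision volume per unit solution volume.
#'
#' @param C Number density, 1/m^3.
#' @param V0 Collision volume, m^3.
#' @return Dimensionless fraction in (0, 1].
#' @export
effective_fraction_from_volume <- function(C, V0) {
  .check_pos(C, "C"); .check_pos(V0, "V0")
  a <- C * V0
  if (any(a > 1)) {
    stop("collision volume exceeds the per-molecule solution volume (a > 1)",
         call. = FALSE)
  }
  a
}

#' Discrete 2D rate
#'
#' r = (4/pi)*A*D*C^(4/3): the 0D rate with the area-ratio effective
#' fraction substituted at L = C^(-1/3). Note the coefficient is 4/pi:
#' it is forced by that substitution (a = 4A/(4*pi*L^2) into r = 4aDC^(2/3))
#' and is the only coefficient that reproduces the worked single-molecule
#' example shipped in [yoyo_lambda_dataset()].
#'
#' @param A Binding area, m^2.
#' @param D m^2/s.
#' @param C 1/m^3.
#' @return Rate, 1/s.
#' @export
rate_2d <- function(A, D, C) {
  .check_pos(A, "A"); .check_pos(D, "D"); .check_pos(C, "C")
  (4 / pi) * A * D * C^(4 / 3)
}

#' Langmuir-Schaefer transient adsorption rate
#'
#' r = 2*A*C*sqrt(D/(pi*t)): flux onto an absorbing patch of area A under
#' a 1D Fick gradient that keeps evolving, so the rate decays as
#' 1/sqrt(t). Suitable for aggregation/multilayer adsorption where a real
#' sub-surface gradient forms.
#'
#' @param A Absorbing area, m^2.
#' @param C 1/m^3.
#' @param D m^2/s.
#' @param t Elapsed time, s.
#' @return Rate, 1/s.
#' @export
rate_langmuir_schaefer <- function(A, C, D, t) {
  .check_pos(A, "A"); .check_pos(C, "C"); .check_pos(D, "D"); .check_pos(t, "t")
  2 * A * C * sqrt(D / (pi * t))
}

#' Discrete 2D rate, reshuffle-time form
#'
#' r = 2*sqrt(2/pi)*A*D*C^(4/3): the Langmuir-Schaefer rate with the
#' continuous t replaced by the reshuffle time t_c = 1/(2*D*C^(2/3)).
#' Same scaling as [rate_2d()]; the coefficient ratio
#' rate_2d_tc/rate_2d = sqrt(pi/2) ~ 1.25 reflects the different packing
#' assumptions of the two derivations.
#'
#' @inheritParams rate_2d
#' @return Rate, 1/s.
#' @export
rate_2d_tc <- function(A, D, C) {
  .check_pos(A, "A"); .check_pos(D, "D"); .check_pos(C, "C")
  2 * sqrt(2 / pi) * A * D * C^(4 / 3)
}

#' Smoluchowski rate
#'
#' r = 4*pi*r0*C*D: steady-state diffusive flux onto an absorbing sphere
#' of radius r0, the classical benchmark for diffusion-controlled
#' kinetics. First order in concentration.
#'
#' @param r0 Collision radius, m.
#' @param C 1/m^3.
#' @param D m^2/s.
#' @return Rate, 1/s.
#' @examples
#' rate_smoluchowski(0.29e-9, nM_to_number_density(1), 2.9e-10)  # ~0.63 /s
#' @export
rate_smoluchowski <- function(r0, C, D) {
  .check_pos(r0, "r0"); .check_pos(C, "C"); .check_pos(D, "D")
  4 * pi * r0 * C * D
}

#' Discrete 3D rate
#'
#' r = 2*C*V0/t_c = 4*V0*D*C^(5/3): volume-overlap counting once per
#' reshuffle time (factor 2 fractal correction included). Equal to the 0D
#' rate with a = C*V0.
#'
#' @param V0 Collision volume, m^3.
#' @param D m^2/s.
#' @param C 1/m^3.
#' @return Rate, 1/s.
#' @export
rate_3d <- function(V0, D, C) {
  .check_pos(V0, "V0"); .check_pos(D, "D"); .check_pos(C, "C")
  4 * V0 * D * C^(5 / 3)
}

#' Discrete 3D rate, area-like rewrite
#'
#' r = (16*pi/3)*(r0^3/L)*D*C^(4/3): the 3D rate with a spherical collision
#' volume V0 = (4/3)*pi*r0^3 and one factor C^(1/3) written as 1/L. Exposes
#' the ratio to the 2D rate: proportional to r0/L, hence much smaller when
#' r0 << L (in the 3D picture probes can pass through the target, so only
#' volume overlap counts).
#'
#' @param r0 Collision radius, m, with r0 < L.
#' @param L Nearest-neighbor distance, m.
#' @param D m^2/s.
#' @param C 1/m^3.
#' @return Rate, 1/s.
#' @export
rate_3d_area_form <- function(r0, L, D, C) {
  .check_pos(r0, "r0", zero_ok = TRUE)
  .check_pos(L, "L"); .check_pos(D, "D"); .check_pos(C, "C")
  if (any(r0 >= L)) stop("requires r0 < L", call. = FALSE)
  (16 * pi / 3) * (r0^3 / L) * D * C^(4 / 3)
}

#' Forward rate for any registry model
#'
#' Dispatch on model id: evaluates the model's rate equation at geometry
#' parameter `geometry` (in the model's own symbol: a, r0, A or V0, SI).
#' Time-dependent models require `t`.
#'
#' @param model Model id or alias (see [model_ids()]).
#' @param geometry Geometry parameter value (SI units of the model symbol).
#' @param D Diffusion coefficient, m^2/s.
#' @param C Number density, 1/m^3.
#' @param t Elapsed time, s; required for `naive_continuous` and
#'   `langmuir_schaefer`.
#' @return Rate, 1/s.
#' @export
predict_rate <- function(model, geometry, D, C, t = NULL) {
  m <- .match_model(model)
  switch(m,
    naive_continuous = {
      if (is.null(t)) stop("model 'naive_continuous' requires `t`", call. = FALSE)
      rate_naive(C, geometry, t)
    },
    discrete_0d = rate_0d(geometry, D, C),
    smoluchowski_1d = rate_smoluchowski(geometry, C, D),
    discrete_2d = rate_2d(geometry, D, C),
    discrete_2d_tc = rate_2d_tc(geometry, D, C),
    langmuir_schaefer = {
      if (is.null(t)) stop("model 'langmuir_schaefer' requires `t`", call. = FALSE)
      rate_langmuir_schaefer(geometry, C, D, t)
    },
    discrete_3d = rate_3d(geometry, D, C)
  )
}

#' Dimensional signature of a model
#'
#' The exponents of concentration, diffusion coefficient and time, and the
#' geometry symbol, as used in the dimensional audit of the model family.
#' `unit_exponents` gives the resulting SI exponents of (meter, second) of
#' the predicted rate; every model must come out at m^0 s^-1.
#'
#' @param model Model id or alias.
#' @return A list of class `dimensional_signature` with fields
#'   `model`, `coefficient`, `concentration_exponent`, `diffusion_exponent`,
#'   `time_exponent`, `geometry_symbol`, `time_dependent`, `unit_exponents`
#'   (named numeric: meter, second).
#' @examples
#' dimensional_signature("discrete_3d")$concentration_exponent  # 5/3
#' @export
dimensional_signature <- function(model) {
  m <- .match_model(model)
  reg <- model_registry()[[m]]
  geom_m <- c(a = 0, r0 = 1, A = 2, V0 = 3)[[reg$geometry_symbol]]
  meter <- geom_m + 2 * reg$diffusion_exponent - 3 * reg$concentration_exponent
  second <- -reg$diffusion_exponent + reg$time_exponent
  structure(c(list(model = m), reg,
              list(unit_exponents = c(meter = meter, second = second))),
            class = "dimensional_signature")
}

#' @export
print.dimensional_signature <- function(x, ...) {
  cat(sprintf("<dimensional_signature> %s: r = %.6g * %s * D^%.3g * C^%.3g%s\n",
              x$model, x$coefficient, x$geometry_symbol,
              x$diffusion_exponent, x$concentration_exponent,
              if (x$time_exponent != 0) sprintf(" * t^%.3g", x$time_exponent)
              else ""))
  cat(sprintf("  SI audit: m^%g s^%g\n",
              x$unit_exponents[["meter"]], x$unit_exponents[["second"]]))
  invisible(x)
}
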