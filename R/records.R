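#' Species descriptor
#'
#' A molecule's size/transport descriptors. At least one of `radius`,
#' the pair (`molecular_weight`, `density`), or `diffusion_coefficient`
#' must be given; the missing quantities are resolved lazily:
#' radius from molecular weight and bulk density (sphere of the neat
#' material), and the diffusion coefficient from the radius by
#' Stokes-Einstein at the supplied solution conditions.
#'
#' @param name Species label.
#' @param molecular_weight kg/mol (note SI: 1271 g/mol = 1.271 kg/mol).
#' @param density Neat-material density, kg/m^3.
#' @param radius Hydrodynamic radius, m.
#' @param diffusion_coefficient m^2/s.
#' @return An object of class `species_spec`.
#' @examples
#' yoyo <- species_spec("YOYO-1", molecular_weight = 1.271, density = 1000)
#' species_radius(yoyo)  # ~0.8 nm, consistent with the ~0.9 nm literature value
#' @export
species_spec <- function(name, molecular_weight = NULL, density = NULL,
                         radius = NULL, diffusion_coefficient = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  chk <- function(x, nm) if (!is.null(x)) .check_pos(x, nm)
  chk(molecular_weight, "molecular_weight"); chk(density, "density")
  chk(radius, "radius"); chk(diffusion_coefficient, "diffusion_coefficient")
  if (is.null(radius) && is.null(diffusion_coefficient) &&
      (is.null(molecular_weight) || is.null(density))) {
    stop("need one of: radius, (molecular_weight, density), diffusion_coefficient",
         call. = FALSE)
  }
  structure(list(name = name, molecular_weight = molecular_weight,
                 density = density, radius = radius,
                 diffusion_coefficient = diffusion_coefficient),
            class = "species_spec")
}

#' @rdname species_spec
#' @param x A `species_spec`.
#' @export
species_radius <- function(x) {
  stopifnot(inherits(x, "species_spec"))
  if (!is.null(x$radius)) return(x$radius)
  if (!is.null(x$molecular_weight) && !is.null(x$density)) {
    return(radius_from_molweight(x$molecular_weight, x$density))
  }
  stop("radius not resolvable: supply radius or (molecular_weight, density)",
       call. = FALSE)
}

#' @rdname species_spec
#' @param conditions A `solution_conditions`, used when the diffusion
#'   coefficient must be derived from the radius.
#' @export
species_diffusion <- function(x, conditions = NULL) {
  stopifnot(inherits(x, "species_spec"))
  if (!is.null(x$diffusion_coefficient)) return(x$diffusion_coefficient)
  if (is.null(conditions)) {
    stop("diffusion coefficient not stored; supply `conditions` to derive it",
         call. = FALSE)
  }
  stokes_einstein_D(conditions$temperature, conditions$viscosity,
                    species_radius(x))
}

#' @export
print.species_spec <- function(x, ...) {
  cat("<species_spec>", x$name, "\n")
  if (!is.null(x$molecular_weight))
    cat("  Mw:", x$molecular_weight, "kg/mol\n")
  if (!is.null(x$radius)) cat("  radius:", x$radius, "m\n")
  if (!is.null(x$diffusion_coefficient))
    cat("  D:", x$diffusion_coefficient, "m^2/s\n")
  invisible(x)
}

#' Solution conditions
#'
#' @param temperature K.
#' @param viscosity Pa s.
#' @param number_concentration 1/m^3 (>= 0).
#' @return An object of class `solution_conditions`.
#' @export
solution_conditions <- function(temperature, viscosity,
                                number_concentration = 0) {
  .check_pos(temperature, "temperature")
  .check_pos(viscosity, "viscosity")
  .check_pos(number_concentration, "number_concentration", zero_ok = TRUE)
  structure(list(temperature = temperature, viscosity = viscosity,
                 number_concentration = number_concentration),
            class = "solution_conditions")
}

#' Rate dataset
#'
#' An ordered set of (concentration, measured per-target rate) pairs, the
#' unit of analysis for reaction-order fitting and model inversion.
#'
#' @param concentration Number densities, 1/m^3, strictly increasing, > 0.
#' @param rate Measured per-target rates, 1/s, >= 0.
#' @param probe Optional `species_spec` for the diffusing probe.
#' @param label Dataset label.
#' @return An object of class `rate_dataset`: a list with a `measurements`
#'   data.frame (columns `concentration`, `rate`), `probe`, `label`.
#' @examples
#' ds <- rate_dataset(nM_to_number_density(c(1, 10)), c(0.63, 4))
#' ds
#' @export
rate_dataset <- function(concentration, rate, probe = NULL, label = "") {
  .check_pos(concentration, "concentration")
  .check_pos(rate, "rate", zero_ok = TRUE)
  if (length(concentration) != length(rate)) {
    stop("concentration and rate must have equal length", call. = FALSE)
  }
  if (length(concentration) < 1L) stop("need at least one measurement", call. = FALSE)
  if (any(diff(concentration) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (!is.null(probe)) stopifnot(inherits(probe, "species_spec"))
  structure(list(measurements = data.frame(concentration = concentration,
                                           rate = rate),
                 probe = probe, label = label),
            class = "rate_dataset")
}

#' @export
print.rate_dataset <- function(x, ...) {
  cat("<rate_dataset>", if (nzchar(x$label)) x$label else "(unlabelled)",
      "-", nrow(x$measurements), "measurements\n")
  df <- data.frame(conc_nM = number_density_to_nM(x$measurements$concentration),
                   rate_per_s = x$measurements$rate)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
length.rate_dataset <- function(x) nrow(x$measurements)

#' @export
as.data.frame.rate_dataset <- function(x, ...) x$measurements
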