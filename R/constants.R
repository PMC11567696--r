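#' Physical constants (SI)
#'
#' CODATA values used throughout the package. All internal computation is in
#' SI units (m, s, kg, K, mol, number/m^3); bench units (nM, nm, us) are
#' converted only at I/O boundaries.
#'
#' @format Named numeric values:
#' \describe{
#'   \item{`AVOGADRO`}{Avogadro constant, 1/mol.}
#'   \item{`BOLTZMANN`}{Boltzmann constant, J/K.}
#'   \item{`GAS_CONSTANT`}{Molar gas constant, J/(mol K).}
#' }
#' @name constants
NULL

#' @rdname constants
#' @export
AVOGADRO <- 6.02214076e23

#' @rdname constants
#' @export
BOLTZMANN <- 1.380649e-23

#' @rdname constants
#' @export
GAS_CONSTANT <- 8.31446

# internal: positive finite scalar check
.check_pos <- function(x, name, zero_ok = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  if (zero_ok) {
    if (any(x < 0)) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  } else {
    if (any(x <= 0)) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# complementary error function on stats::pnorm
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
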