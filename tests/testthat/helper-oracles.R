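# Independent quadrature/closed-form oracles used against the package's
# implementations. These deliberately re-derive quantities from first
# principles (numerical integration of the defining integrals) rather
# than reusing package code paths.

# normalization of the 3D Gaussian propagator; the integration range is
# scaled to the diffusion length so the adaptive quadrature resolves the
# peak at any (D, t); the truncated tail at 12 sigma is ~1e-60
quad_propagator_norm <- function(D, t) {
  s <- sqrt(4 * D * t)
  stats::integrate(function(R) {
    4 * pi * R^2 * (4 * pi * D * t)^(-3 / 2) * exp(-R^2 / (4 * D * t))
  }, 0, 12 * s, rel.tol = 1e-12, subdivisions = 500L)$value
}

# second radial moment <R^2> of the propagator
quad_propagator_msd <- function(D, t) {
  s <- sqrt(4 * D * t)
  stats::integrate(function(R) {
    R^2 * 4 * pi * R^2 * (4 * pi * D * t)^(-3 / 2) * exp(-R^2 / (4 * D * t))
  }, 0, 12 * s, rel.tol = 1e-12, subdivisions = 500L)$value
}

# hard-sphere collision frequency by quadrature of the defining
# Maxwell-Boltzmann integral (collisions per second)
quad_collision_freq <- function(sigma, m, Temp, CB) {
  kB <- 1.380649e-23
  stats::integrate(function(v) {
    sigma * v * CB * 4 * pi * v^2 * (m / (2 * pi * kB * Temp))^(3 / 2) *
      exp(-m * v^2 / (2 * kB * Temp))
  }, 0, Inf, rel.tol = 1e-9)$value
}

# erfc via base R for oracle-side computations
erfc_oracle <- function(x) 2 * pnorm(-sqrt(2) * x)

# log-uniform random draws for property grids
runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# the published six-point dataset, rebuilt locally so fixture edits in the
# package would be caught
printed_table <- function() {
  data.frame(
    conc_nM    = c(1,    3,    5,    10,   50,   100),
    L_um       = c(1.2,  0.8,  0.7,  0.55, 0.32, 0.25),
    tc_us      = c(240,  120,  83,   53,   18,   11),
    rate_per_s = c(0.63, 1.49, 2.85, 4,    10,   15),
    a_1e3      = c(0.77, 0.87, 1.2,  1.1,  0.90, 0.85),
    r0_1d_nm   = c(0.29, 0.23, 0.26, 0.18, 0.09, 0.07),
    A_nm2      = c(3400, 1900, 1800, 1000, 290,  170),
    r0_2d_nm   = c(3.4,  1.9,  1.8,  1.0,  0.29, 0.17),
    V_1e4_nm3  = c(130,  49,   40,   18,   3,    1.4),
    r0_3d_nm   = c(36,   22,   20,   13,   5.5,  3.8)
  )
}
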