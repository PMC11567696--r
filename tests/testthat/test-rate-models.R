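D_pub <- 2.9e-10  # published probe diffusion coefficient, m^2/s

test_that("forward rates reproduce the published worked-example cells", {
  expect_equal(rate_0d(0.87e-3, D_pub, nM_to_number_density(3)), 1.49,
               tolerance = 0.1)
  expect_equal(rate_smoluchowski(0.29e-9, nM_to_number_density(1), D_pub),
               0.63, tolerance = 0.1)
  expect_equal(rate_smoluchowski(0.07e-9, nM_to_number_density(100), D_pub),
               15, tolerance = 0.1)
  expect_equal(rate_2d(3.4e-15, D_pub, nM_to_number_density(1)), 0.63,
               tolerance = 0.1)
  expect_equal(rate_3d(1.4e-23, D_pub, nM_to_number_density(100)), 15,
               tolerance = 0.1)
})

test_that("simple forward values and degenerate cases", {
  expect_equal(rate_naive(6.022e17, 1e-27, 1), 6.022e-10)
  expect_equal(rate_naive(6.022e17, 1e-27, 2), 6.022e-10 / 2)
  expect_error(rate_naive(6.022e17, 1e-27, 0), "> 0")
  expect_equal(rate_0d(0, 1e-10, 1e18), 0)
  expect_error(rate_0d(1.2, 1e-10, 1e18), "\\[0, 1\\]")
  expect_equal(rate_langmuir_schaefer(3.4e-15, nM_to_number_density(1),
                                      D_pub, 1), 3.93e-2, tolerance = 1e-2)
  expect_equal(rate_langmuir_schaefer(1e-15, 1e18, 1e-10, 4),
               rate_langmuir_schaefer(1e-15, 1e18, 1e-10, 1) / 2)
  expect_equal(rate_3d_area_form(0, 1e-6, 1e-10, 1e18), 0)
  expect_error(rate_3d_area_form(2e-6, 1e-6, 1e-10, 1e18), "r0 < L")
})

test_that("effective fractions: saturation, linearity, guards", {
  L <- mean_separation(nM_to_number_density(1))
  expect_equal(effective_fraction_from_area(3.4e-15, 1.18e-6), 7.77e-4,
               tolerance = 1e-2)
  expect_equal(effective_fraction_from_area(pi * L^2, L), 1)
  expect_equal(effective_fraction_from_area(1e-15, 2 * L),
               effective_fraction_from_area(1e-15, L) / 4)
  expect_error(effective_fraction_from_area(2 * pi * L^2, L), "a > 1")
  expect_equal(effective_fraction_from_volume(6.022e17, 1.27e-21), 7.648e-4,
               tolerance = 1e-3)
  expect_equal(effective_fraction_from_volume(6.022e17, 1 / 6.022e17), 1)
  expect_error(effective_fraction_from_volume(1e18, 1e-17), "a > 1")
})

test_that("composition identities hold to 1e-12 over random parameter grids", {
  set.seed(42)
  n <- 200
  # dilute ranges keep the effective fractions in (0, 1)
  A <- runif_log(n, 1e-18, 1e-16)
  V0 <- runif_log(n, 1e-27, 1e-24)
  r0 <- runif_log(n, 1e-10, 1e-9)
  D <- runif_log(n, 1e-12, 1e-9)
  C <- runif_log(n, 1e18, 1e21)
  L <- C^(-1 / 3)
  # area-fraction route equals the closed 2D form
  expect_equal(rate_0d(effective_fraction_from_area(A, L), D, C),
               rate_2d(A, D, C), tolerance = 1e-12)
  # volume-fraction route equals the closed 3D form
  expect_equal(rate_0d(effective_fraction_from_volume(C, V0), D, C),
               rate_3d(V0, D, C), tolerance = 1e-12)
  # Langmuir-Schaefer at the reshuffle time equals the 2D tc-form
  expect_equal(rate_langmuir_schaefer(A, C, D, critical_time(D, C)),
               rate_2d_tc(A, D, C), tolerance = 1e-12)
  # spherical-volume rewrite of the 3D rate at L = C^(-1/3)
  expect_equal(rate_3d_area_form(r0, L, D, C),
               rate_3d((4 / 3) * pi * r0^3, D, C), tolerance = 1e-12)
})

test_that("2D coefficient conventions: tc-form / plain ratio is sqrt(pi/2)", {
  set.seed(7)
  A <- runif_log(20, 1e-18, 1e-14)
  D <- runif_log(20, 1e-12, 1e-9)
  C <- runif_log(20, 1e18, 1e22)
  ratio <- rate_2d_tc(A, D, C) / rate_2d(A, D, C)
  expect_equal(ratio, rep(sqrt(pi / 2), 20), tolerance = 1e-12)
})

test_that("forward/inverse round trips hold to 1e-12 for invertible models", {
  set.seed(13)
  invertible <- c("discrete_0d", "smoluchowski_1d", "discrete_2d",
                  "discrete_2d_tc", "discrete_3d")
  for (m in invertible) {
    for (i in 1:20) {
      D <- runif_log(1, 1e-12, 1e-9)
      C <- runif_log(1, 1e18, 1e22)
      g <- switch(m, discrete_0d = runif(1, 1e-5, 1e-2),
                  smoluchowski_1d = runif_log(1, 1e-10, 1e-8),
                  discrete_2d = runif_log(1, 1e-18, 1e-15),
                  discrete_2d_tc = runif_log(1, 1e-18, 1e-15),
                  discrete_3d = runif_log(1, 1e-27, 1e-22))
      r <- predict_rate(m, g, D, C)
      expect_equal(unname(invert_model(m, r, C, D)), g, tolerance = 1e-12)
    }
  }
  # time-dependent model inverts through its explicit-time path
  r <- rate_langmuir_schaefer(3.4e-15, 1e18, 1e-10, 2)
  expect_equal(unname(invert_langmuir_schaefer(r, 1e18, 1e-10, 2)), 3.4e-15,
               tolerance = 1e-12)
  expect_error(invert_model("langmuir_schaefer", 1, 1e18, 1e-10),
               "time-dependent")
  expect_error(invert_model("naive", 1, 1e18, 1e-10), "time-dependent")
  expect_equal(unname(invert_model("discrete_0d", 0, 1e18, 1e-10)), 0)
})

test_that("inversion reproduces the published geometry cells", {
  r0 <- invert_model("smoluchowski_1d", 0.63, nM_to_number_density(1), D_pub)
  expect_equal(unname(r0) * 1e9, 0.29, tolerance = 0.1)
  V0 <- invert_model("discrete_3d", 15, nM_to_number_density(100), D_pub)
  expect_equal(unname(V0) * 1e27, 1.4e4, tolerance = 0.1)
})

test_that("cylinder conventions map areas and volumes to printed radii", {
  expect_equal(cylinder_radius_from_area(3400e-18, 1000e-9) * 1e9, 3.4,
               tolerance = 0.02)
  expect_equal(cylinder_radius_from_area(170e-18, 1000e-9) * 1e9, 0.17,
               tolerance = 0.02)
  expect_equal(cylinder_radius_from_volume(130e4 * 1e-27, 1000e-9) * 1e9, 36,
               tolerance = 0.02)
  expect_equal(cylinder_radius_from_volume(1.4e4 * 1e-27, 1000e-9) * 1e9, 3.74,
               tolerance = 0.02)
  expect_equal(cylinder_radius_from_area(1e-15, 2e-6),
               cylinder_radius_from_area(1e-15, 1e-6) / 2)
  expect_equal(cylinder_radius_from_volume(4e-22, 1e-6),
               2 * cylinder_radius_from_volume(1e-22, 1e-6))
})

test_that("every rate is monotone in C, D and its geometry parameter", {
  C <- 1e19; D <- 1e-10
  cases <- list(
    list(m = "discrete_0d", g = 1e-3),
    list(m = "smoluchowski_1d", g = 1e-9),
    list(m = "discrete_2d", g = 1e-16),
    list(m = "discrete_2d_tc", g = 1e-16),
    list(m = "discrete_3d", g = 1e-24))
  for (cs in cases) {
    base <- predict_rate(cs$m, cs$g, D, C)
    expect_gt(predict_rate(cs$m, cs$g, D, 1.5 * C), base)
    expect_gt(predict_rate(cs$m, cs$g, 1.5 * D, C), base)
    expect_gt(predict_rate(cs$m, 1.5 * cs$g, D, C), base)
  }
  # the naive model is independent of D by construction
  expect_equal(dimensional_signature("naive_continuous")$diffusion_exponent, 0)
})

test_that("log-log slope in C equals the registry concentration exponent", {
  D <- 1e-10
  geoms <- list(naive_continuous = 1e-24, discrete_0d = 1e-3,
                smoluchowski_1d = 1e-9, discrete_2d = 1e-16,
                discrete_2d_tc = 1e-16, langmuir_schaefer = 1e-16,
                discrete_3d = 1e-24)
  for (m in model_ids()) {
    C1 <- 1e19; C2 <- C1 * exp(1)
    r1 <- predict_rate(m, geoms[[m]], D, C1, t = 1)
    r2 <- predict_rate(m, geoms[[m]], D, C2, t = 1)
    slope <- log(r2 / r1)
    expect_equal(slope, dimensional_signature(m)$concentration_exponent,
                 tolerance = 1e-9)
  }
})

test_that("dimensional signatures audit to 1/s for every model", {
  expect_equal(dimensional_signature("smoluchowski_1d")$concentration_exponent,
               1)
  expect_equal(dimensional_signature("discrete_3d")$concentration_exponent,
               5 / 3)
  for (m in model_ids()) {
    u <- dimensional_signature(m)$unit_exponents
    expect_equal(unname(u[["meter"]]), 0)
    expect_equal(unname(u[["second"]]), -1)
  }
  expect_error(dimensional_signature("no_such_model"), "unknown model")
})

test_that("3D rate is far below the 2D rate for the same r0 when r0 << L", {
  set.seed(5)
  D <- runif_log(20, 1e-12, 1e-9)
  C <- runif_log(20, 1e18, 1e21)
  r0 <- runif_log(20, 1e-10, 1e-9)
  L <- C^(-1 / 3)
  expect_true(all(r0 < L / 50))
  r2d <- rate_2d(pi * r0^2, D, C)
  r3d <- rate_3d((4 / 3) * pi * r0^3, D, C)
  expect_true(all(r3d < r2d))
  # the ratio is proportional to r0/L (= r0 * C^(1/3))
  expect_equal(r3d / r2d, (4 * pi / 3) * r0 / L, tolerance = 1e-12)
})

test_that("thermodynamic utilities: Arrhenius limits and Ka identities", {
  expect_equal(arrhenius_pseudo_first_order(5, 0, 298), 5)
  expect_equal(arrhenius_pseudo_first_order(5, 8.31446 * 298, 298), 5 / exp(1))
  expect_equal(arrhenius_pseudo_first_order(5, 5e4, 1e12), 5, tolerance = 1e-6)
  expect_error(arrhenius_pseudo_first_order(5, 0, -1), "> 0")
  expect_equal(equilibrium_constant_from_free_energy(0, 298) * 1000, 1)
  expect_equal(equilibrium_constant_from_free_energy(
    -8.31446 * 298 * log(10), 298) * 1000, 10)
  # Ka = 1/Kd: the dimensionless ratios from +dG and -dG are reciprocal
  dG <- -3e4
  Ka_red <- equilibrium_constant_from_free_energy(dG, 298) * 1000
  Kd_red <- equilibrium_constant_from_free_energy(-dG, 298) * 1000
  expect_equal(Ka_red * Kd_red, 1, tolerance = 1e-12)
})
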