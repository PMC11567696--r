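# The MC tests run in nondimensional units (r0 = 1, D = 1); every
# closed-form comparison is against an analytic oracle with a 3-standard-
# error band, and all runs are seeded.

test_that("free diffusion: MSD follows 6Dt and D = 0 stays put", {
  cfg <- sim_config(1, 0, walker_count = 2000, box_side = 1,
                    time_step = 0.01, total_time = 1, seed = 21)
  out <- simulate_free_diffusion(cfg)
  k <- length(out$times)
  expect_lt(abs(out$msd[k] - 6 * out$times[k]), 3 * out$msd_stderr[k])
  # every checkpoint within 4 SE (joint band over 20 checkpoints)
  expect_true(all(abs(out$msd - 6 * out$times) < 4 * out$msd_stderr))
  cfg0 <- sim_config(0, 0, walker_count = 10, box_side = 1,
                     time_step = 0.01, total_time = 0.1, seed = 21)
  out0 <- simulate_free_diffusion(cfg0)
  expect_true(all(out0$final_positions == 0))
})

test_that("radial displacement distribution matches the Gaussian propagator", {
  cfg <- sim_config(1, 0, walker_count = 10000, box_side = 1,
                    time_step = 0.02, total_time = 1, seed = 33)
  out <- simulate_free_diffusion(cfg)
  tt <- out$times[length(out$times)]
  # R^2/(2Dt) is chi-squared with 3 df under the propagator
  ks <- suppressWarnings(
    stats::ks.test(out$final_radii^2 / (2 * 1 * tt), stats::pchisq, df = 3))
  crit_1pct <- 1.628 / sqrt(cfg$walker_count)
  expect_lt(unname(ks$statistic), crit_1pct)
})

test_that("simulations are bitwise reproducible under a fixed seed", {
  cfg <- sim_config(1, 0.05, target_radius = 1, box_side = 16,
                    time_step = 0.01, total_time = 20, seed = 5)
  a <- simulate_absorbing_sphere(cfg)
  b <- simulate_absorbing_sphere(cfg)
  expect_identical(a$first_encounter_times, b$first_encounter_times)
  expect_identical(a$rate_estimate, b$rate_estimate)
  cfg2 <- sim_config(1, 0.05, target_radius = 1, box_side = 16,
                     time_step = 0.01, total_time = 20, seed = 6)
  c2 <- simulate_absorbing_sphere(cfg2)
  expect_false(identical(a$first_encounter_times, c2$first_encounter_times))

  f1 <- simulate_free_diffusion(sim_config(1, 0, walker_count = 100,
                                           box_side = 1, time_step = 0.01,
                                           total_time = 0.5, seed = 9))
  f2 <- simulate_free_diffusion(sim_config(1, 0, walker_count = 100,
                                           box_side = 1, time_step = 0.01,
                                           total_time = 0.5, seed = 9))
  expect_identical(f1$final_positions, f2$final_positions)
})

test_that("absorbing sphere refuses unresolvably coarse steps", {
  expect_error(
    simulate_absorbing_sphere(sim_config(1, 0.01, target_radius = 1,
                                         box_side = 16, time_step = 0.2,
                                         total_time = 1, seed = 1)),
    "time_step too coarse")
  # a vanishing target yields no encounters
  tiny <- sim_config(1, 0.01, target_radius = 0.05, box_side = 10,
                     time_step = 1e-4, total_time = 0.1, seed = 2)
  expect_equal(simulate_absorbing_sphere(tiny)$encounter_count, 0)
})

test_that("steady-state encounter rate matches the Smoluchowski closed form", {
  cfg <- sim_config(1, 0.1, target_radius = 1, box_side = 24,
                    time_step = 0.005, total_time = 100, seed = 17)
  out <- simulate_absorbing_sphere(cfg)
  expect_gt(out$encounter_count, 50)
  expect_lt(abs(out$rate_estimate - out$theory_rate), 3 * out$rate_stderr)
})

test_that("early encounter rate exceeds the steady-state plateau", {
  # transient enhancement ~ r0/sqrt(pi D t); summed over replicate boxes
  # because a single run's excess is below Poisson noise
  early <- 0; late <- 0
  for (k in 1:16) {
    cfg <- sim_config(1, 0.2, target_radius = 1, box_side = 20,
                      time_step = 0.005, total_time = 10, seed = 300 + k)
    out <- simulate_absorbing_sphere(cfg)
    early <- early + sum(out$first_encounter_times <= 1)
    late <- late + sum(out$first_encounter_times > 9)
  }
  expect_gt(early, late)
})

test_that("mirror-plane mode runs and absorbs on the hemisphere", {
  cfg <- sim_config(1, 0.1, target_radius = 1, box_side = 16,
                    time_step = 0.005, total_time = 20, seed = 44,
                    boundary_mode = "mirror_plane")
  out <- simulate_absorbing_sphere(cfg)
  expect_gt(out$encounter_count, 0)
  expect_true(is.finite(out$rate_estimate))
})

test_that("capture fraction from distance L matches the erfc closed form", {
  # horizon chosen as L^2/(2D), the reshuffle time of a solution with
  # nearest-neighbor distance L
  L <- 4; r0 <- 1; D <- 1; horizon <- L^2 / (2 * D)
  cap <- capture_fraction_from_neighbor(L, r0, D, horizon, n = 4000, seed = 12)
  expect_equal(cap$closed_form,
               (r0 / L) * erfc_oracle((L - r0) / sqrt(4 * D * horizon)))
  expect_lt(abs(cap$estimate - cap$closed_form), 3 * cap$stderr)
  # step halving moves the estimate by less than the joint 3 SE band,
  # bounding the endpoint-detection bias empirically
  cap2 <- capture_fraction_from_neighbor(L, r0, D, horizon, n = 4000,
                                         seed = 12,
                                         time_step = r0^2 / (400 * D))
  expect_lt(abs(cap2$estimate - cap$estimate),
            3 * sqrt(cap$stderr^2 + cap2$stderr^2))
  # degenerate and guard cases
  expect_equal(capture_fraction_from_neighbor(4, 0, 1, 1)$estimate, 0)
  expect_error(capture_fraction_from_neighbor(1, 2, 1, 1), "r0 < L")
  # the long-time limit of the closed form is r0/L
  expect_equal((r0 / L) * erfc_oracle((L - r0) / sqrt(4 * D * 1e8)), r0 / L,
               tolerance = 1e-3)
})

test_that("1D first-passage probabilities match erfc at five time points", {
  fp <- simulate_first_passage_1d(L = 1, D = 1,
                                  times = c(0.25, 0.5, 1, 2, 4),
                                  time_step = 0.002, n = 5000, seed = 77)
  expect_equal(fp$prob_closed_form[3], erfc_oracle(1 / sqrt(4 * 1 * 1)),
               tolerance = 1e-6)
  expect_true(all(abs(fp$prob_mc - fp$prob_closed_form) < 3 * fp$stderr))
})

test_that("coarse-graining: mean exit time matches L^2/(2D), ratio is stable", {
  # fine_step at t_c/1250 keeps the residual O(dt) discretization bias
  # (after the continuity correction) below the statistical band
  cg <- estimate_coarse_graining_factor(L = 1, D = 1, total_time = 10,
                                        fine_step = 4e-4, n = 300, seed = 31)
  expect_lt(abs(cg$mean_exit_time - cg$analytic_exit_time),
            3 * cg$mean_exit_time_stderr)
  # identical seed reproduces the ratio exactly
  cg2 <- estimate_coarse_graining_factor(L = 1, D = 1, total_time = 10,
                                         fine_step = 4e-4, n = 300, seed = 31)
  expect_identical(cg$ratio, cg2$ratio)
  # diffusive scaling: L -> 2L with total_time -> 4x leaves the ratio
  # statistically unchanged (same nondimensional problem)
  cg4 <- estimate_coarse_graining_factor(L = 2, D = 1, total_time = 40,
                                         fine_step = 1.6e-3, n = 300, seed = 31)
  expect_lt(abs(cg4$ratio - cg$ratio), 0.15)
  # scale-separation guards
  expect_error(estimate_coarse_graining_factor(1, 1, 10, 0.1, n = 10),
               "fine_step")
  expect_error(estimate_coarse_graining_factor(1, 1, 1, 0.001, n = 10),
               "total_time")
})

test_that("simulated encounter rate is first order in concentration", {
  base <- sim_config(1, 0.2, target_radius = 1, box_side = 24,
                     time_step = 0.005, total_time = 50, seed = 60)
  scan <- scan_concentration_scaling(base, conc_grid = c(0.05, 0.1, 0.2))
  expect_gt(scan$fit$order, 0.7)
  expect_lt(scan$fit$order, 1.3)
  # doubling concentration doubles the rate within 3 joint SE
  r1 <- scan$table$rate[1]; r2 <- scan$table$rate[2]
  se <- sqrt((2 * scan$table$stderr[1])^2 + scan$table$stderr[2]^2)
  expect_lt(abs(r2 - 2 * r1), 3 * se)
  # fixed seed gives a deterministic fitted order
  scan2 <- scan_concentration_scaling(base, conc_grid = c(0.05, 0.1, 0.2))
  expect_identical(scan$fit$order, scan2$fit$order)
})
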