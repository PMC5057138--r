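test_that("suspension feeding multiplies the settling velocity only where toggled", {
  mask <- structure(list(coral = matrix(c(TRUE, FALSE), 1, 2),
                         habitat_class = matrix(c("coral_mound", "off_reef"),
                                                1, 2)),
                    class = "habitat_mask")
  p <- om_params()
  expect_identical(p$ws_coral, 200)
  on <- effective_ws(mask, p, filtration_on = TRUE)
  off <- effective_ws(mask, p, filtration_on = FALSE)
  expect_identical(on[1, 1], 200)      # coral column, filtration on
  expect_identical(off[1, 1], 20)      # coral column, filtration off
  expect_identical(on[1, 2], 20)       # off-reef column, filtration on
})

test_that("decay is exponential and composes exactly", {
  st <- tracer_state(array(1, c(2, 2, 2)), 0)
  expect_identical(apply_decay(st, 0, 1)$concentration, st$concentration)
  expect_equal(apply_decay(st, 0.03, 1)$concentration[1], exp(-0.03),
               tolerance = 1e-12)
  two <- apply_decay(apply_decay(st, 0.03, 0.5), 0.03, 0.5)
  one <- apply_decay(st, 0.03, 1)
  expect_equal(two$concentration, one$concentration, tolerance = 1e-15)
})

test_that("the surface flux loads the top layer and conserves mass", {
  # uniform grid with 12-m top layer: H = 48 m, 4 levels
  g <- build_grid(bathymetry(matrix(48, 3, 2), 100, 100), 4, theta_s = 0)
  st <- tracer_state(array(0, c(3, 2, 4)), 0)
  out <- apply_surface_flux(st, g, surface_flux = 12, dt = 1)
  expect_equal(out$concentration[2, 2, 4], 1.0, tolerance = 1e-14)
  expect_identical(sum(out$concentration[, , 1:3]), 0)
  expect_identical(apply_surface_flux(st, g, 0, 1)$concentration,
                   st$concentration)
  gain <- tracer_inventory(out, g) - tracer_inventory(st, g)
  expect_equal(gain, 12 * (100 * 100) * 6 * 1, tolerance = 1e-9) # flux*area*dt
})

test_that("the quiescent column closed form has the expected surface value and scale", {
  p <- om_params()
  sol <- steady_column_solution(p, c(0, 500, 1000))
  expect_equal(sol$concentration[1], 0.6, tolerance = 1e-12)  # 12 / 20
  ef <- attr(sol, "e_folding_depth")
  expect_equal(ef, 20 / 0.03, tolerance = 1e-12)
  expect_gt(ef, 500); expect_lt(ef, 700)
  # vanishing decay: concentration constant in depth
  p0 <- om_params(k_decay = 1e-12)
  sol0 <- steady_column_solution(p0, c(0, 2000))
  expect_equal(sol0$concentration[2], 0.6, tolerance = 1e-6)
})

test_that("capture efficiency reproduces the clearance-volume arithmetic", {
  ce <- capture_efficiency(0.3, 0.2, 200)
  expect_equal(ce$available_volume, 5184, tolerance = 1e-12)
  expect_equal(ce$efficiency, 100 * 200 / 5184, tolerance = 1e-12)
  expect_identical(capture_efficiency(0.3, 0.2, 0)$efficiency, 0)
  expect_error(capture_efficiency(0, 0.2, 200), "current")
})

test_that("null forcing keeps every field at zero", {
  g <- build_grid(bathymetry(matrix(800, 2, 2), 250, 250), 6)
  mask <- structure(list(coral = matrix(FALSE, 2, 2),
                         habitat_class = matrix("off_reef", 2, 2)),
                    class = "habitat_mask")
  p <- om_params(surface_flux = 0)
  cfg <- scenario_config(FALSE, FALSE, 0, 2, output_cadence = 1, spinup = 0)
  run <- integrate_scenario(g, make_zero_flow(g, 0, 2), mask, p, cfg)
  expect_identical(max(abs(run$final_state$concentration)), 0)
  expect_identical(sum(run$dep_mass_post), 0)
})

test_that("the mass budget closes on a small tidal run", {
  dom <- default_domain(nx = 12, ny = 10, n_levels = 8)
  flows <- make_tidal_flow(dom$grid, dom$forcing, 0, 1)
  cfg <- scenario_config(TRUE, TRUE, 0, 1, output_cadence = 0.25,
                         spinup = 0.25)
  run <- integrate_scenario(dom$grid, flows, dom$mask, om_params(), cfg)
  b <- run$budget
  expect_true(all(abs(b$residual[-1]) < 1e-6 * b$cum_input[-1]))
  expect_true(all(run$final_state$concentration >= 0))
  expect_lt(run$surface_w_residual, 1e-10)     # rigid-lid consistency
})

test_that("with enhancement 1 the filtration toggle is bit-identical", {
  dom <- default_domain(nx = 8, ny = 8, n_levels = 6)
  flows <- make_tidal_flow(dom$grid, dom$forcing, 0, 0.5)
  p <- om_params(enhancement = 1)
  cfg <- function(f) scenario_config(f, TRUE, 0, 0.5, output_cadence = 0.25,
                                     spinup = 0)
  on <- integrate_scenario(dom$grid, flows, dom$mask, p, cfg(TRUE))
  off <- integrate_scenario(dom$grid, flows, dom$mask, p, cfg(FALSE))
  expect_identical(on$final_state$concentration,
                   off$final_state$concentration)
  expect_identical(on$dep_mass_post, off$dep_mass_post)
})

test_that("the quiescent run converges to the closed form and refines", {
  err32 <- column_error(32)
  expect_lt(err32, 0.02)
  err64 <- column_error(64)
  expect_lt(err64, err32)
})

test_that("quiescent filtration focuses deposition transiently, then draws down", {
  g <- build_grid(bathymetry(matrix(700, 2, 1), 250, 250), 10)
  mask <- structure(list(coral = matrix(c(TRUE, FALSE), 2, 1),
                         habitat_class = matrix(c("coral_mound", "off_reef"),
                                                2, 1)),
                    class = "habitat_mask")
  p <- om_params()
  cfg <- scenario_config(TRUE, FALSE, 0, 1, output_cadence = 0.5, spinup = 0)
  run <- integrate_scenario(g, make_zero_flow(g, 0, 1), mask, p, cfg)
  ratio <- run$dep_mean_flux[1, 1] / run$dep_mean_flux[2, 1]
  expect_gt(ratio, 1)                     # filtration elevates deposition
  expect_lt(ratio, p$enhancement)         # but drawdown keeps it below 10
  # the instantaneous ratio from a uniform concentration is exactly 10:
  st <- tracer_state(array(0.5, c(2, 1, 10)), 0)
  wf <- array(0, c(2, 1, 11))
  wf[, , 1] <- -effective_ws(mask, p, TRUE)
  one <- advect_upwind(st, g, array(0, c(3, 1, 10)), array(0, c(2, 2, 10)),
                       wf, 0.01)
  expect_equal(one$deposition_mass[1, 1] / one$deposition_mass[2, 1], 10,
               tolerance = 1e-12)
})

test_that("invalid parameters and configurations are rejected", {
  expect_error(om_params(ws = -1), "positive")
  expect_error(om_params(k_decay = 0), "positive")
  expect_error(scenario_config(t_start = 1, t_end = 1), "t_end")
  expect_error(scenario_config(t_end = 2, spinup = 3), "spinup")
})
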