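test_that("diagnosed w vanishes for zero and for uniform flow over a flat bed", {
  g <- flat_grid(nx = 5, ny = 4, nz = 6)
  zero <- list(u = array(0, c(6, 4, 6)), v = array(0, c(5, 5, 6)))
  expect_identical(max(abs(diagnose_w(g, zero)$w)), 0)
  unif <- list(u = array(0.2, c(6, 4, 6)), v = array(-0.1, c(5, 5, 6)))
  expect_lt(max(abs(diagnose_w(g, unif)$w)), 1e-14)
})

test_that("w over a depth step matches the hand-computed column sum", {
  depth <- matrix(rep(c(1000, 1000, 500, 500), 3), 4, 3)
  g <- build_grid(bathymetry(depth, 250, 250), 5, theta_s = 0)
  # depth-uniform u carrying constant transport Q per unit width
  Q <- 100
  H_u <- apply(g$Hz_u, c(1, 2), sum)
  u <- array(rep(Q / H_u, 5), c(5, 3, 5))
  snap <- list(u = u, v = array(0, c(4, 4, 5)))
  wf <- diagnose_w(g, snap)
  for (i in c(2, 3)) {
    expect_equal(wf$w[i, 2, ], oracle_w_column(g, snap, i, 2),
                 tolerance = 1e-12)
  }
  expect_lt(wf$surface_residual, 1e-13)
  expect_identical(wf$w[2, 2, 1], 0)               # seabed condition
})

test_that("flow interpolation is exact at nodes, linear, and affine between them", {
  g <- flat_grid(nx = 3, ny = 3, nz = 2)
  mk <- function(val, t) structure(
    list(u = array(val, c(4, 3, 2)), v = array(-val, c(3, 4, 2)), time = t),
    class = "flow_snapshot")
  series <- structure(list(times = c(0, 0.25, 0.5),
                           snapshots = list(mk(0, 0), mk(0.2, 0.25),
                                            mk(0.1, 0.5))),
                      class = "flow_series")
  expect_identical(interp_flow(series, 0.25)$u[1], 0.2)
  expect_equal(interp_flow(series, 0.125)$u[1], 0.1)
  p <- vapply(c(0.05, 0.1, 0.2), function(t) interp_flow(series, t)$u[1],
              numeric(1))
  expect_equal(p[2] - p[1], (p[3] - p[2]) / 2, tolerance = 1e-14) # collinear
  expect_error(interp_flow(series, 0.6), "outside")
})

test_that("upwind advection is inert for zero flow and preserves constants", {
  g <- flat_grid()
  st <- tracer_state(array(runif(4 * 3 * 4), c(4, 3, 4)), 0)
  out <- advect_upwind(st, g, array(0, c(5, 3, 4)), array(0, c(4, 4, 4)),
                       array(0, c(4, 3, 5)), 0.1)
  expect_identical(out$state$concentration, st$concentration)
  expect_identical(sum(out$deposition_mass), 0)

  # constant tracer in a divergence-free 3-D flow stays constant
  dom <- default_domain(nx = 10, ny = 8, n_levels = 6)
  flows <- make_tidal_flow(dom$grid, dom$forcing, 0, 0.5)
  snap <- flows$snapshots[[2]]
  wfld <- diagnose_w(dom$grid, snap)
  st <- tracer_state(array(1, c(10, 8, 6)), 0)
  dt <- cfl_max_dt(dom$grid, snap, wfld, 0)
  out <- advect_upwind(st, dom$grid, snap$u * 86400, snap$v * 86400,
                       wfld$w * 86400, dt)
  expect_lt(max(abs(out$state$concentration - 1)), 1e-12)
})

test_that("a five-cell column reproduces the hand-rolled donor-cell update", {
  g <- build_grid(bathymetry(matrix(500, 1, 1), 100, 100), 5, theta_s = 0)
  C <- array(c(0.1, 0.5, 0.2, 0.8, 0.4), c(1, 1, 5))
  wf <- array(c(-40, -20, 30, -10, 5, 999), c(1, 1, 6))  # top face ignored
  dt <- 0.4  # courant 0.4*40/100 = 0.16
  st <- advect_upwind(tracer_state(C, 0), g,
                      array(0, c(2, 1, 5)), array(0, c(1, 2, 5)), wf, dt)
  # hand computation, cells bottom to top, Hz = 100 m, area = 1e4 m^2
  flux <- function(w, cdn, cup) 1e4 * (max(w, 0) * cdn + min(w, 0) * cup)
  Fi <- c(flux(-40, 0.1, 0.1), flux(-20, 0.1, 0.5), flux(30, 0.5, 0.2),
          flux(-10, 0.2, 0.8), flux(5, 0.8, 0.4), 0)
  Chand <- as.vector(C) - dt * (Fi[2:6] - Fi[1:5]) / (100 * 1e4)
  expect_equal(as.vector(st$state$concentration), Chand, tolerance = 1e-14)
  expect_equal(st$deposition_mass[1, 1], -Fi[1] * dt, tolerance = 1e-14)
})

test_that("one step matches the independent loop oracle on small instances", {
  for (seed in 1:8) {
    dims <- list(c(5, 5, 5), c(3, 4, 5), c(5, 1, 3), c(1, 1, 5))[[1 + seed %% 4]]
    inst <- random_instance(dims[1], dims[2], dims[3], seed)
    g <- inst$grid
    got <- advect_upwind(tracer_state(inst$C, 0), g, inst$u, inst$v, inst$wf,
                         inst$dt)
    want <- oracle_upwind(inst$C, inst$u, inst$v, inst$wf, g$Hz_u, g$Hz_v,
                          g$Hz, g$dx, g$dy, inst$dt)
    expect_lt(max(abs(got$state$concentration - want$conc)), 1e-12)
    expect_lt(max(abs(got$deposition_mass - want$deposition)), 1e-9)
    expect_lt(abs(got$boundary_mass - want$boundary),
              1e-12 * max(1, abs(want$boundary)))
  }
})

test_that("mass is conserved with closed boundaries and no settling", {
  set.seed(7)
  g <- build_grid(bathymetry(matrix(runif(12, 600, 1400), 4, 3), 250, 250),
                  5, 3.4, 1)
  # interior-only velocities: zero on all domain-boundary faces
  u <- array(0, c(5, 3, 5)); u[2:4, , ] <- runif(45, -1, 1) * 3000
  v <- array(0, c(4, 4, 5)); v[, 2:3, ] <- runif(40, -1, 1) * 3000
  wf <- array(0, c(4, 3, 6)); wf[, , 2:5] <- runif(48, -1, 1) * 30
  st <- tracer_state(array(runif(60, 0.1, 1), c(4, 3, 5)), 0)
  m0 <- tracer_inventory(st, g)
  for (s in 1:20) st <- advect_upwind(st, g, u, v, wf, 0.01)$state
  expect_lt(abs(tracer_inventory(st, g) - m0) / m0, 1e-10)
})

test_that("upwind advection creates no new extrema under the CFL bound", {
  dom <- default_domain(nx = 12, ny = 10, n_levels = 8)
  flows <- make_tidal_flow(dom$grid, dom$forcing, 0, 1)
  set.seed(11)
  C <- array(runif(12 * 10 * 8), c(12, 10, 8))
  st <- tracer_state(C, 0)
  lo <- min(C); hi <- max(C)
  for (it in 1:4) {
    snap <- flows$snapshots[[it]]
    wfld <- diagnose_w(dom$grid, snap)
    dt <- cfl_max_dt(dom$grid, snap, wfld, 0)
    for (s in 1:5)
      st <- advect_upwind(st, dom$grid, snap$u * 86400, snap$v * 86400,
                          wfld$w * 86400, dt)$state
    expect_gte(min(st$concentration), lo - 1e-12)
    expect_lte(max(st$concentration), hi + 1e-12)
  }
})

test_that("the CFL step matches definitions and a brute-force face scan", {
  g <- flat_grid(nx = 3, ny = 3, nz = 4, H = 400)
  expect_identical(cfl_max_dt(g, NULL, NULL, 0, dt_cap = 0.05), 0.05)
  # single active x-face with |u| = dx per day
  u <- array(0, c(4, 3, 4)); u[2, 2, 3] <- g$dx / 86400
  snap <- list(u = u, v = array(0, c(3, 4, 4)))
  expect_equal(cfl_max_dt(g, snap, NULL, 0, dt_cap = 10), 0.8,
               tolerance = 1e-12)
  # mixed 3-D field against an exhaustive per-face minimum
  inst <- random_instance(4, 3, 5, 99)
  g2 <- inst$grid
  snap2 <- list(u = inst$u / 86400, v = inst$v / 86400)
  wfld <- diagnose_w(g2, snap2)
  got <- cfl_max_dt(g2, snap2, wfld, ws_max = 50, dt_cap = 10)
  Hzmin <- pmin(g2$Hz[, , c(1, 1:4)], g2$Hz[, , 1:5])
  rate <- max(max(abs(inst$u)) / g2$dx, max(abs(inst$v)) / g2$dy,
              max((abs(wfld$w[, , 1:5]) * 86400 + 50) / Hzmin))
  expect_equal(got, 0.8 / rate, tolerance = 1e-12)
})

test_that("dimension mismatches and CFL violations raise errors", {
  g <- flat_grid(nx = 3, ny = 3, nz = 4)
  expect_error(diagnose_w(g, list(u = array(0, c(2, 2, 2)),
                                  v = array(0, c(3, 4, 4)))), "dimensions")
  st <- tracer_state(array(1, c(3, 3, 4)), 0)
  u <- array(0, c(4, 3, 4)); u[2, 2, 2] <- 5000
  expect_error(advect_upwind(st, g, u, array(0, c(3, 4, 4)),
                             array(0, c(3, 3, 5)), 1), "CFL")
})
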