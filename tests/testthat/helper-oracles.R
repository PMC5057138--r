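# Independent oracles and small fixture builders. The donor-cell oracle is a
# deliberate re-derivation in plain R loops: it shares no code with the
# package's advection path and is used to pin the upwind scheme down to
# round-off.

# one donor-cell step with zero-gradient lateral boundaries, no flux through
# the top interface, and the bottom-face flux recorded as deposition;
# velocities in m/day, dt in days
oracle_upwind <- function(C, u, v, wf, Hzu, Hzv, Hz, dx, dy, dt) {
  nx <- dim(C)[1]; ny <- dim(C)[2]; nz <- dim(C)[3]
  area <- dx * dy
  Cn <- C
  dep <- matrix(0, nx, ny)
  boundary <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
    # west/east faces i, i+1 in the (nx+1) face array
    fW <- u[i, j, k] * Hzu[i, j, k] * dy
    cW <- if (u[i, j, k] > 0) C[max(i - 1, 1), j, k] else C[i, j, k]
    fE <- u[i + 1, j, k] * Hzu[i + 1, j, k] * dy
    cE <- if (u[i + 1, j, k] > 0) C[i, j, k] else C[min(i + 1, nx), j, k]
    fS <- v[i, j, k] * Hzv[i, j, k] * dx
    cS <- if (v[i, j, k] > 0) C[i, max(j - 1, 1), k] else C[i, j, k]
    fN <- v[i, j + 1, k] * Hzv[i, j + 1, k] * dx
    cN <- if (v[i, j + 1, k] > 0) C[i, j, k] else C[i, min(j + 1, ny), k]
    # bottom/top interfaces k, k+1 in the (nz+1) interface array
    wB <- wf[i, j, k]
    cB <- if (wB > 0) C[i, j, max(k - 1, 1)] else C[i, j, k]
    FB <- wB * area * cB
    if (k == nz) FT <- 0
    else {
      wT <- wf[i, j, k + 1]
      cT <- if (wT > 0) C[i, j, k] else C[i, j, k + 1]
      FT <- wT * area * cT
    }
    dF <- fE * cE - fW * cW + fN * cN - fS * cS + FT - FB
    Cn[i, j, k] <- C[i, j, k] - dt * dF / (Hz[i, j, k] * area)
    if (k == 1) dep[i, j] <- dep[i, j] - FB * dt
    if (i == 1) boundary <- boundary - fW * cW * dt
    if (i == nx) boundary <- boundary + fE * cE * dt
    if (j == 1) boundary <- boundary - fS * cS * dt
    if (j == ny) boundary <- boundary + fN * cN * dt
  }
  list(conc = Cn, deposition = dep, boundary = boundary)
}

# per-column cumulative continuity sum, written independently of diagnose_w
oracle_w_column <- function(grid, snap, i, j) {
  nz <- grid$n_levels
  w <- numeric(nz + 1)
  flux <- 0
  for (k in seq_len(nz)) {
    out <- snap$u[i + 1, j, k] * grid$Hz_u[i + 1, j, k] * grid$dy -
      snap$u[i, j, k] * grid$Hz_u[i, j, k] * grid$dy +
      snap$v[i, j + 1, k] * grid$Hz_v[i, j + 1, k] * grid$dx -
      snap$v[i, j, k] * grid$Hz_v[i, j, k] * grid$dx
    flux <- flux - out
    w[k + 1] <- flux / (grid$dx * grid$dy)
  }
  w
}

# small uniform-depth grid
flat_grid <- function(nx = 4, ny = 3, nz = 4, H = 1000, dx = 250, dy = 250,
                      theta_s = 0, theta_b = 0) {
  build_grid(bathymetry(matrix(H, nx, ny), dx, dy), nz, theta_s, theta_b)
}

# random small test instance for the oracle-equivalence property
random_instance <- function(nx, ny, nz, seed) {
  set.seed(seed)
  g <- build_grid(bathymetry(matrix(runif(nx * ny, 500, 1500), nx, ny),
                             250, 250),
                  nz, theta_s = 2, theta_b = 0.5)
  u <- array(runif((nx + 1) * ny * nz, -1, 1) * 5000, c(nx + 1, ny, nz))
  v <- array(runif(nx * (ny + 1) * nz, -1, 1) * 5000, c(nx, ny + 1, nz))
  wf <- array(runif(nx * ny * (nz + 1), -1, 1) * 20, c(nx, ny, nz + 1))
  C <- array(runif(nx * ny * nz, 0, 2), c(nx, ny, nz))
  # a stable step for these draws
  dt <- 0.8 / max(max(abs(u)) / 250, max(abs(v)) / 250,
                  max(abs(wf)) / min(g$Hz))
  list(grid = g, u = u, v = v, wf = wf, C = C, dt = dt)
}

# quiescent single-column scenario run against the closed form
column_error <- function(n_levels, H = 1000, t_end = 400) {
  g <- build_grid(bathymetry(matrix(H, 1, 1), 250, 250), n_levels)
  mask <- structure(list(coral = matrix(FALSE, 1, 1),
                         habitat_class = matrix("off_reef", 1, 1)),
                    class = "habitat_mask")
  p <- om_params()
  cfg <- scenario_config(filtration_on = FALSE, hydrodynamics_on = FALSE,
                         t_start = 0, t_end = t_end, output_cadence = t_end,
                         spinup = 0, store_tracer = FALSE)
  run <- integrate_scenario(g, make_zero_flow(g, 0, t_end), mask, p, cfg,
                            dt_cap = 0.5)
  Cex <- steady_column_solution(p, as.vector(g$z_c))$concentration
  max(abs(as.vector(run$final_state$concentration) - Cex)) / max(Cex)
}
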