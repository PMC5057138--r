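# Offline transport on the staggered sigma grid: vertical velocity diagnosed
# from horizontal flux divergence, linear time interpolation of stored flow
# snapshots, and mass-conservative first-order upwind (donor-cell) advection.

SECONDS_PER_DAY <- 86400

#' Diagnose vertical velocity from horizontal flux divergence
#'
#' Under the rigid-lid assumption (fixed free surface) and zero vertical
#' velocity at the seabed, continuity fixes the vertical volume flux through
#' every layer interface: integrating upward from the bottom, the flux through
#' interface k+1 equals the flux through interface k minus the net horizontal
#' volume outflow of layer k. Dividing by the cell plan area gives w on the
#' interfaces. The residual |w| at the surface measures how far the supplied
#' flow field is from non-divergent depth-integrated transport; it is reported,
#' not forced to zero.
#'
#' @param grid a [build_grid()] sigma grid.
#' @param snapshot a `flow_snapshot` with `u` \[nx+1,ny,nz\] and
#'   `v` \[nx,ny+1,nz\] in m/s.
#' @return object of class `w_field`: list with `w` \[nx,ny,nz+1\] (m/s,
#'   positive up, `w[,,1] = 0`) and `surface_residual`, the maximum absolute
#'   surface w (m/s).
#' @export
diagnose_w <- function(grid, snapshot) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$n_levels
  if (!identical(dim(snapshot$u), as.integer(c(nx + 1, ny, nz))) ||
      !identical(dim(snapshot$v), as.integer(c(nx, ny + 1, nz))))
    stop("snapshot velocity dimensions do not match the grid", call. = FALSE)
  w <- diagnose_w_cpp(as.numeric(snapshot$u), as.numeric(snapshot$v),
                      as.numeric(grid$Hz_u), as.numeric(grid$Hz_v),
                      nx, ny, nz, grid$dx, grid$dy)
  dim(w) <- c(nx, ny, nz + 1)
  structure(list(w = w,
                 surface_residual = max(abs(w[, , nz + 1]))),
            class = "w_field")
}

#' Interpolate a flow series in time
#'
#' Componentwise linear interpolation between the two snapshots bracketing
#' `t`, mirroring the offline coupling of stored hydrodynamic output.
#'
#' @param series a `flow_series`.
#' @param t time in days; must lie within the series' span.
#' @return a `flow_snapshot` at time `t`.
#' @export
interp_flow <- function(series, t) {
  times <- series$times
  n <- length(times)
  if (t < times[1] || t > times[n])
    stop("t = ", t, " outside the flow series span [", times[1], ", ",
         times[n], "]", call. = FALSE)
  i <- findInterval(t, times, rightmost.closed = TRUE)
  if (i == n) i <- n - 1
  a <- series$snapshots[[i]]; b <- series$snapshots[[i + 1]]
  wgt <- (t - times[i]) / (times[i + 1] - times[i])
  structure(list(u = (1 - wgt) * a$u + wgt * b$u,
                 v = (1 - wgt) * a$v + wgt * b$v,
                 time = t),
            class = "flow_snapshot")
}

#' Largest stable time step (CFL bound)
#'
#' Scans every face of the grid and returns the largest time step for which
#' the face Courant number (velocity times dt over the face-normal cell size)
#' stays at or below `safety`. The vertical bound includes the maximum
#' settling velocity on top of the diagnosed vertical velocity; vertical face
#' Courant numbers use the thinner of the two adjacent layers.
#'
#' @param grid sigma grid.
#' @param snapshot `flow_snapshot` (m/s); may be NULL for quiescent runs.
#' @param w_field a [diagnose_w()] result (m/s); may be NULL.
#' @param ws_max maximum settling speed (m/d) to include on vertical faces.
#' @param safety Courant safety factor. Default 0.8.
#' @param dt_cap upper bound on the returned step (days). Default 0.05.
#' @return time step in days.
#' @export
cfl_max_dt <- function(grid, snapshot = NULL, w_field = NULL, ws_max = 0,
                       safety = 0.8, dt_cap = 0.05) {
  rate <- 0  # max inverse residence time, 1/days
  if (!is.null(snapshot)) {
    rate <- max(rate,
                max(abs(snapshot$u)) * SECONDS_PER_DAY / grid$dx,
                max(abs(snapshot$v)) * SECONDS_PER_DAY / grid$dy)
  }
  nz <- grid$n_levels
  # thinnest layer adjacent to each interior/bottom vertical face
  Hz_min_face <- pmin(grid$Hz[, , c(1, 1:(nz - 1)), drop = FALSE],
                      grid$Hz[, , 1:nz, drop = FALSE])
  wmag <- ws_max
  if (!is.null(w_field))
    wmag <- abs(w_field$w[, , 1:nz, drop = FALSE]) * SECONDS_PER_DAY + ws_max
  if (any(wmag > 0)) rate <- max(rate, max(wmag / Hz_min_face))
  if (rate <= 0) return(dt_cap)
  min(dt_cap, safety / rate)
}

#' One first-order upwind advection step
#'
#' Donor-cell fluxes on all faces of the C-grid, in conservative form: the
#' tracer mass change of the interior equals the net of the boundary fluxes.
#' Horizontal domain boundaries are zero-gradient (ghost cells copy the
#' adjacent interior value, so outflow exports tracer and inflow imports the
#' boundary-cell concentration). The top interface carries no advective flux
#' (the surface input is a separate boundary forcing); the bottom interface
#' carries the settling flux, which is recorded as deposition. No explicit
#' diffusion is added: the scheme's numerical dispersion stands in for it.
#'
#' @param state a [tracer_state()] (concentration in mmol C/m^3).
#' @param grid sigma grid.
#' @param u,v face velocities in m/day, \[nx+1,ny,nz\] and \[nx,ny+1,nz\]
#'   shaped as the grid's staggering.
#' @param w_face vertical interface velocities in m/day \[nx,ny,nz+1\]
#'   (positive up), including the settling contribution; `w_face[,,1]` is the
#'   (negative) bottom settling velocity, `w_face[,,nz+1]` is ignored.
#' @param dt time step (days); must satisfy the CFL bound.
#' @return list with `state` (updated), `deposition_mass` \[nx,ny\]
#'   (mmol C per column deposited this step), `boundary_mass` (net mmol C
#'   exported through the lateral boundaries this step).
#' @export
advect_upwind <- function(state, grid, u, v, w_face, dt) {
  C <- state$concentration
  nx <- grid$nx; ny <- grid$ny; nz <- grid$n_levels
  if (!identical(dim(C), as.integer(c(nx, ny, nz))))
    stop("tracer dimensions do not match the grid", call. = FALSE)

  res <- upwind_step_cpp(as.numeric(C), as.numeric(u), as.numeric(v),
                         as.numeric(w_face),
                         as.numeric(grid$Hz_u), as.numeric(grid$Hz_v),
                         as.numeric(grid$Hz), nx, ny, nz,
                         grid$dx, grid$dy, dt)
  if (max(res$courant) > 1 + 1e-9) {
    lim <- c("x-face", "y-face", "vertical face")[which.max(res$courant)]
    stop("CFL violation: Courant number ", signif(max(res$courant), 4),
         " > 1 at a ", lim, call. = FALSE)
  }
  Cnew <- res$conc
  dim(Cnew) <- c(nx, ny, nz)
  deposition_mass <- res$deposition_mass
  dim(deposition_mass) <- c(nx, ny)
  list(state = tracer_state(Cnew, state$time + dt),
       deposition_mass = deposition_mass,
       boundary_mass = res$boundary_mass)
}

#' Tracer state container
#'
#' @param concentration 3-D array \[nx,ny,nz\] of organic-carbon
#'   concentration (mmol C/m^3), layer 1 at the bottom.
#' @param time time stamp in days.
#' @return object of class `tracer_state`.
#' @export
tracer_state <- function(concentration, time = 0) {
  if (any(!is.finite(concentration)))
    stop("tracer concentrations must be finite", call. = FALSE)
  structure(list(concentration = concentration, time = time),
            class = "tracer_state")
}

#' Total tracer inventory
#'
#' @param state tracer state.
#' @param grid sigma grid.
#' @return total mass in mmol C.
#' @export
tracer_inventory <- function(state, grid) {
  sum(state$concentration * cell_volume(grid))
}
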