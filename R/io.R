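# NetCDF and CSV round-tripping of grids, flow series and run records.
# Dimension names follow the package convention: x, y, layer, interface,
# time; velocity components live on their staggered face dimensions.

#' Write a sigma grid to NetCDF
#'
#' Stores the bathymetry, layer thicknesses, stretched sigma coordinates and
#' the stretching parameters (as global attributes), plus the habitat mask if
#' supplied.
#'
#' @param grid sigma grid.
#' @param path output file.
#' @param mask optional habitat mask stored alongside (`coral` as 0/1,
#'   `habitat_class` as integer code 0 = off_reef, 1 = coral_mound,
#'   2 = coral_ridge).
#' @return `path`, invisibly.
#' @export
write_grid_nc <- function(grid, path, mask = NULL) {
  dim_x <- ncdf4::ncdim_def("x", "m", grid$x)
  dim_y <- ncdf4::ncdim_def("y", "m", grid$y)
  dim_l <- ncdf4::ncdim_def("layer", "", seq_len(grid$n_levels))
  dim_i <- ncdf4::ncdim_def("interface", "", seq_len(grid$n_levels + 1))
  vars <- list(
    depth = ncdf4::ncvar_def("depth", "m", list(dim_x, dim_y), prec = "double"),
    Hz = ncdf4::ncvar_def("Hz", "m", list(dim_x, dim_y, dim_l), prec = "double"),
    sigma = ncdf4::ncvar_def("sigma", "", list(dim_i), prec = "double"))
  if (!is.null(mask)) {
    vars$coral <- ncdf4::ncvar_def("coral", "", list(dim_x, dim_y),
                                   prec = "integer")
    vars$habitat_class <- ncdf4::ncvar_def("habitat_class", "",
                                           list(dim_x, dim_y),
                                           prec = "integer")
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vars$depth, grid$depth)
  ncdf4::ncvar_put(nc, vars$Hz, grid$Hz)
  ncdf4::ncvar_put(nc, vars$sigma, grid$sigma_interfaces)
  if (!is.null(mask)) {
    ncdf4::ncvar_put(nc, vars$coral, mask$coral * 1L)
    code <- matrix(match(mask$habitat_class,
                         c("off_reef", "coral_mound", "coral_ridge")) - 1L,
                   grid$nx, grid$ny)
    ncdf4::ncvar_put(nc, vars$habitat_class, code)
  }
  ncdf4::ncatt_put(nc, 0, "dx", grid$dx)
  ncdf4::ncatt_put(nc, 0, "dy", grid$dy)
  ncdf4::ncatt_put(nc, 0, "n_levels", grid$n_levels)
  ncdf4::ncatt_put(nc, 0, "theta_s", grid$theta_s)
  ncdf4::ncatt_put(nc, 0, "theta_b", grid$theta_b)
  invisible(path)
}

#' Read a sigma grid (and habitat mask) from NetCDF
#'
#' Rebuilds the grid from the stored bathymetry and stretching parameters and
#' checks that the stored layer thicknesses agree with the rebuilt ones.
#'
#' @param path NetCDF file written by [write_grid_nc()] (or any file exposing
#'   `depth` with `dx`, `dy`, `n_levels`, `theta_s`, `theta_b` attributes).
#' @return list with `grid` and `mask` (NULL if the file has no mask).
#' @export
read_grid_nc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  depth <- ncdf4::ncvar_get(nc, "depth")
  att <- function(name) ncdf4::ncatt_get(nc, 0, name)$value
  x <- nc$dim$x$vals; y <- nc$dim$y$vals
  bathy <- bathymetry(depth, att("dx"), att("dy"), x, y)
  grid <- build_grid(bathy, att("n_levels"), att("theta_s"), att("theta_b"))
  if ("Hz" %in% names(nc$var)) {
    Hz <- ncdf4::ncvar_get(nc, "Hz")
    if (max(abs(Hz - grid$Hz)) > 1e-6)
      warning("stored layer thicknesses differ from the rebuilt grid",
              call. = FALSE)
  }
  mask <- NULL
  if ("coral" %in% names(nc$var)) {
    coral <- ncdf4::ncvar_get(nc, "coral") > 0
    code <- ncdf4::ncvar_get(nc, "habitat_class")
    habitat_class <- matrix(c("off_reef", "coral_mound",
                              "coral_ridge")[code + 1L],
                            nrow(depth), ncol(depth))
    mask <- structure(list(coral = matrix(coral, nrow(depth), ncol(depth)),
                           habitat_class = habitat_class),
                      class = "habitat_mask")
  }
  list(grid = grid, mask = mask)
}

#' Write a flow series to NetCDF
#'
#' @param flows a `flow_series`.
#' @param grid the sigma grid the flow lives on.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flow_nc <- function(flows, grid, path) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$n_levels
  nt <- length(flows$times)
  dim_xu <- ncdf4::ncdim_def("x_u", "m", (0:nx) * grid$dx)
  dim_yv <- ncdf4::ncdim_def("y_v", "m", (0:ny) * grid$dy)
  dim_x <- ncdf4::ncdim_def("x", "m", grid$x)
  dim_y <- ncdf4::ncdim_def("y", "m", grid$y)
  dim_l <- ncdf4::ncdim_def("layer", "", seq_len(nz))
  dim_t <- ncdf4::ncdim_def("time", "days", flows$times, unlim = TRUE)
  var_u <- ncdf4::ncvar_def("u", "m s-1", list(dim_xu, dim_y, dim_l, dim_t),
                            prec = "double")
  var_v <- ncdf4::ncvar_def("v", "m s-1", list(dim_x, dim_yv, dim_l, dim_t),
                            prec = "double")
  nc <- ncdf4::nc_create(path, list(var_u, var_v))
  on.exit(ncdf4::nc_close(nc))
  for (it in seq_len(nt)) {
    ncdf4::ncvar_put(nc, var_u, flows$snapshots[[it]]$u,
                     start = c(1, 1, 1, it), count = c(nx + 1, ny, nz, 1))
    ncdf4::ncvar_put(nc, var_v, flows$snapshots[[it]]$v,
                     start = c(1, 1, 1, it), count = c(nx, ny + 1, nz, 1))
  }
  invisible(path)
}

#' Read a flow series from NetCDF
#'
#' Accepts files written by [write_flow_nc()] or externally supplied gridded
#' flow with the same dimension layout.
#'
#' @param path NetCDF file.
#' @param grid sigma grid the flow must match.
#' @return a `flow_series`.
#' @export
read_flow_nc <- function(path, grid) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  times <- as.vector(nc$dim$time$vals)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$n_levels
  snapshots <- lapply(seq_along(times), function(it) {
    u <- ncdf4::ncvar_get(nc, "u", start = c(1, 1, 1, it),
                          count = c(nx + 1, ny, nz, 1), collapse_degen = FALSE)
    v <- ncdf4::ncvar_get(nc, "v", start = c(1, 1, 1, it),
                          count = c(nx, ny + 1, nz, 1), collapse_degen = FALSE)
    structure(list(u = array(u, c(nx + 1, ny, nz)),
                   v = array(v, c(nx, ny + 1, nz)),
                   time = times[it]), class = "flow_snapshot")
  })
  structure(list(times = times, snapshots = snapshots, forcing = NULL,
                 dims = c(nx = nx, ny = ny, nz = nz)),
            class = "flow_series")
}

#' Write a run record to NetCDF
#'
#' Stores the post-spinup mean deposition field, the final tracer state and
#' the scenario toggles; the budget goes to CSV via [write_budget_csv()].
#'
#' @param run a `scenario_run`.
#' @param grid sigma grid.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_nc <- function(run, grid, path) {
  dim_x <- ncdf4::ncdim_def("x", "m", grid$x)
  dim_y <- ncdf4::ncdim_def("y", "m", grid$y)
  dim_l <- ncdf4::ncdim_def("layer", "", seq_len(grid$n_levels))
  var_dep <- ncdf4::ncvar_def("deposition", "mmol C m-2 d-1",
                              list(dim_x, dim_y), prec = "double")
  var_c <- ncdf4::ncvar_def("concentration", "mmol C m-3",
                            list(dim_x, dim_y, dim_l), prec = "double")
  nc <- ncdf4::nc_create(path, list(var_dep, var_c))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var_dep, run$dep_mean_flux)
  ncdf4::ncvar_put(nc, var_c, run$final_state$concentration)
  ncdf4::ncatt_put(nc, 0, "filtration_on", as.integer(run$config$filtration_on))
  ncdf4::ncatt_put(nc, 0, "hydrodynamics_on",
                   as.integer(run$config$hydrodynamics_on))
  ncdf4::ncatt_put(nc, 0, "t_start", run$config$t_start)
  ncdf4::ncatt_put(nc, 0, "t_end", run$config$t_end)
  ncdf4::ncatt_put(nc, 0, "spinup", run$config$spinup)
  ncdf4::ncatt_put(nc, 0, "ws", run$params$ws)
  ncdf4::ncatt_put(nc, 0, "k_decay", run$params$k_decay)
  ncdf4::ncatt_put(nc, 0, "surface_flux", run$params$surface_flux)
  ncdf4::ncatt_put(nc, 0, "enhancement", run$params$enhancement)
  invisible(path)
}

#' Write the mass-budget ledger to CSV
#'
#' @param run a `scenario_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_budget_csv <- function(run, path) {
  utils::write.csv(run$budget, path, row.names = FALSE)
  invisible(path)
}

#' Export a transect section as CSV
#'
#' Long-format table (distance, depth, value), one row per section cell.
#'
#' @param section a [transect_section()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transect_csv <- function(section, path) {
  nk <- ncol(section$value)
  out <- data.frame(distance = rep(section$distance, times = nk),
                    depth = as.vector(section$depth),
                    value = as.vector(section$value))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
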