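# Terrain-following (sigma) grids with Arakawa C-grid staggering.
#
# Conventions used throughout the package:
#   * horizontal index i along x (1..nx), j along y (1..ny)
#   * vertical layer index k = 1 at the BOTTOM, increasing upward to nz
#   * depths are positive down; the free surface is fixed at z = 0 (rigid lid)
#   * u lives on x-faces [nx+1, ny, nz], v on y-faces [nx, ny+1, nz],
#     w on vertical interfaces [nx, ny, nz+1], scalars at centers [nx, ny, nz]

#' Vertical stretching function for sigma coordinates
#'
#' The classic two-parameter hyperbolic stretching of terrain-following ocean
#' grids (Song and Haidvogel 1994), with the critical depth taken as zero so
#' layer thicknesses are purely proportional to the stretched sigma spacing.
#' `theta_s` sharpens resolution toward the surface and bottom; `theta_b`
#' shifts refinement toward the bottom (`theta_b = 1` refines both
#' boundaries symmetrically).
#'
#' @param s dimensionless sigma coordinate(s) in \[-1, 0\].
#' @param theta_s surface stretching intensity (>= 0); 0 gives no stretching.
#' @param theta_b bottom stretching parameter in \[0, 1\].
#' @return stretched coordinate C(s), monotone, with C(-1) = -1 and C(0) = 0.
#' @export
sigma_stretch <- function(s, theta_s, theta_b) {
  if (theta_s < 0) stop("theta_s must be non-negative", call. = FALSE)
  if (theta_b < 0 || theta_b > 1) stop("theta_b must lie in [0, 1]", call. = FALSE)
  if (theta_s == 0) return(s)
  (1 - theta_b) * sinh(theta_s * s) / sinh(theta_s) +
    theta_b * (tanh(theta_s * (s + 0.5)) / (2 * tanh(theta_s / 2)) - 0.5)
}

#' Build stretched sigma levels
#'
#' Computes the dimensionless interface and center coordinates of a
#' terrain-following vertical grid with `n_levels` layers. Interfaces span
#' \[-1, 0\] (bottom to surface) and are refined near both boundaries when
#' `theta_s > 0` and `theta_b > 0`.
#'
#' @param n_levels number of vertical layers (>= 2).
#' @param theta_s surface stretching intensity (>= 0). Default 3.4.
#' @param theta_b bottom stretching parameter in \[0, 1\]. Default 1.
#' @return list with `sigma_interfaces` (length `n_levels + 1`, strictly
#'   increasing from -1 to 0) and `sigma_centers` (interface midpoints).
#' @examples
#' lv <- build_sigma_levels(32, 3.4, 1)
#' diff(lv$sigma_interfaces)  # thin layers near -1 and 0
#' @export
build_sigma_levels <- function(n_levels, theta_s = 3.4, theta_b = 1) {
  if (length(n_levels) != 1 || !is.finite(n_levels) || n_levels < 2 ||
      n_levels != round(n_levels))
    stop("n_levels must be an integer >= 2", call. = FALSE)
  s <- seq(-1, 0, length.out = n_levels + 1)
  si <- sigma_stretch(s, theta_s, theta_b)
  si[1] <- -1; si[n_levels + 1] <- 0   # exact endpoints
  if (any(diff(si) <= 0))
    stop("stretching produced non-monotone interfaces", call. = FALSE)
  list(sigma_interfaces = si,
       sigma_centers = (si[-1] + si[-(n_levels + 1)]) / 2)
}

#' Bathymetry container
#'
#' @param depth matrix \[nx, ny\] of positive water depth (m, positive down).
#' @param dx,dy horizontal cell sizes (m).
#' @param x,y optional cell-center coordinates (m); defaults to regular axes
#'   starting at dx/2, dy/2.
#' @return object of class `bathymetry`.
#' @export
bathymetry <- function(depth, dx, dy, x = NULL, y = NULL) {
  depth <- as.matrix(depth)
  if (!all(is.finite(depth)) || any(depth <= 0))
    stop("bathymetry depths must be finite and positive", call. = FALSE)
  if (dx <= 0 || dy <= 0) stop("dx and dy must be positive", call. = FALSE)
  nx <- nrow(depth); ny <- ncol(depth)
  if (is.null(x)) x <- (seq_len(nx) - 0.5) * dx
  if (is.null(y)) y <- (seq_len(ny) - 0.5) * dy
  if (length(x) != nx || length(y) != ny)
    stop("coordinate vectors inconsistent with depth dimensions", call. = FALSE)
  structure(list(depth = depth, dx = dx, dy = dy, x = x, y = y,
                 nx = nx, ny = ny),
            class = "bathymetry")
}

#' Build a terrain-following C-grid over a bathymetry
#'
#' Per-column layer thicknesses are `Hz[k] = H * (C(s[k+1]) - C(s[k]))` where
#' C is the stretched sigma coordinate, so layer thicknesses sum exactly to
#' the local depth. Face thicknesses (`Hz_u`, `Hz_v`) are arithmetic means of
#' the adjacent columns (copies at the domain boundary), so the face water
#' depths are consistent with the column sums.
#'
#' @param bathy a [bathymetry] object.
#' @param n_levels number of vertical layers. Default 32.
#' @param theta_s,theta_b stretching parameters, see [build_sigma_levels()].
#' @return object of class `sigma_grid` with elements `depth`, `dx`, `dy`,
#'   `x`, `y`, `nx`, `ny`, `n_levels`, `theta_s`, `theta_b`,
#'   `sigma_interfaces`, `sigma_centers`, `Hz` \[nx,ny,nz\],
#'   `z_w` \[nx,ny,nz+1\] interface depths below surface (positive down,
#'   `z_w[,,1] = H`), `z_c` \[nx,ny,nz\] center depths, and face thicknesses
#'   `Hz_u` \[nx+1,ny,nz\], `Hz_v` \[nx,ny+1,nz\].
#' @examples
#' b <- bathymetry(matrix(1000, 2, 2), dx = 250, dy = 250)
#' g <- build_grid(b, n_levels = 4, theta_s = 0)
#' g$Hz[1, 1, ]  # 250 250 250 250
#' @export
build_grid <- function(bathy, n_levels = 32, theta_s = 3.4, theta_b = 1) {
  if (!inherits(bathy, "bathymetry"))
    stop("bathy must be a bathymetry object", call. = FALSE)
  lv <- build_sigma_levels(n_levels, theta_s, theta_b)
  nx <- bathy$nx; ny <- bathy$ny; nz <- n_levels
  H <- bathy$depth
  dC <- diff(lv$sigma_interfaces)                      # length nz, sums to 1
  Hz <- outer(H, dC)                                   # [nx, ny, nz]
  z_w <- outer(H, -lv$sigma_interfaces)                # interface depth below surface
  z_c <- (z_w[, , -1, drop = FALSE] + z_w[, , -(nz + 1), drop = FALSE]) / 2
  dim(z_c) <- c(nx, ny, nz)

  Hz_u <- array(0, c(nx + 1, ny, nz))
  if (nx > 1)
    Hz_u[2:nx, , ] <- (Hz[-nx, , , drop = FALSE] + Hz[-1, , , drop = FALSE]) / 2
  Hz_u[1, , ] <- Hz[1, , ]; Hz_u[nx + 1, , ] <- Hz[nx, , ]
  Hz_v <- array(0, c(nx, ny + 1, nz))
  if (ny > 1)
    Hz_v[, 2:ny, ] <- (Hz[, -ny, , drop = FALSE] + Hz[, -1, , drop = FALSE]) / 2
  Hz_v[, 1, ] <- Hz[, 1, ]; Hz_v[, ny + 1, ] <- Hz[, ny, ]

  structure(list(depth = H, dx = bathy$dx, dy = bathy$dy,
                 x = bathy$x, y = bathy$y,
                 nx = nx, ny = ny, n_levels = nz,
                 theta_s = theta_s, theta_b = theta_b,
                 sigma_interfaces = lv$sigma_interfaces,
                 sigma_centers = lv$sigma_centers,
                 Hz = Hz, z_w = z_w, z_c = z_c,
                 Hz_u = Hz_u, Hz_v = Hz_v,
                 bathymetry = bathy),
            class = "sigma_grid")
}

#' @export
print.sigma_grid <- function(x, ...) {
  cat("sigma_grid:", x$nx, "x", x$ny, "columns,", x$n_levels, "layers\n")
  cat("  dx =", x$dx, "m, dy =", x$dy, "m\n")
  cat("  depth range:", round(min(x$depth), 1), "-", round(max(x$depth), 1), "m\n")
  cat("  stretching: theta_s =", x$theta_s, ", theta_b =", x$theta_b, "\n")
  invisible(x)
}

# cell plan areas and volumes (internal)
cell_volume <- function(grid) grid$Hz * (grid$dx * grid$dy)
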