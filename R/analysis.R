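# Result analyses: vertical-velocity extrema over a region, transect
# sections in true depth coordinates, deposition versus depth by habitat
# class with focusing factors, and the three-way scenario comparison.

#' Vertical-velocity extrema time series
#'
#' For every snapshot of a flow series, the maximum upwelling and maximum
#' downwelling velocity occurring simultaneously anywhere in a named region
#' (a set of columns).
#'
#' @param grid sigma grid.
#' @param flows a `flow_series`.
#' @param region logical matrix \[nx, ny\] selecting the columns of the
#'   region (e.g. the mound or the ridge area).
#' @return data.frame with columns `time` (days), `w_up` (max positive w,
#'   m/s) and `w_down` (max downwelling magnitude, m/s).
#' @export
velocity_extrema <- function(grid, flows, region) {
  if (!any(region)) stop("region mask is empty", call. = FALSE)
  idx <- which(region)
  rows <- lapply(seq_along(flows$times), function(it) {
    w <- diagnose_w(grid, flows$snapshots[[it]])$w
    wcols <- matrix(w, grid$nx * grid$ny, grid$n_levels + 1)[idx, ,
                                                            drop = FALSE]
    data.frame(time = flows$times[it],
               w_up = max(0, wcols),
               w_down = max(0, -wcols))
  })
  do.call(rbind, rows)
}

#' Extract a vertical section along a transect
#'
#' Pulls a 2-D (distance x depth) section out of a 3-D field along a grid
#' line, with true depth coordinates obtained by unrolling the sigma layers
#' through the local layer thicknesses.
#'
#' @param grid sigma grid.
#' @param field 3-D array on cell centers \[nx,ny,nz\] or on interfaces
#'   \[nx,ny,nz+1\] (e.g. a `w` field).
#' @param along `"y"` (fixed x-index, section runs across the slope) or
#'   `"x"` (fixed y-index).
#' @param index the fixed grid index.
#' @return object of class `transect_section`: list with `distance` (m),
#'   `depth` (matrix, m below surface, positive down), `value` (matrix),
#'   `bottom` (seafloor depth along the transect, m) and `along`/`index`.
#' @export
transect_section <- function(grid, field, along = c("y", "x"), index) {
  along <- match.arg(along)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$n_levels
  nk <- dim(field)[3]
  if (!identical(dim(field)[1:2], as.integer(c(nx, ny))) ||
      !(nk %in% c(nz, nz + 1)))
    stop("field dimensions do not match the grid", call. = FALSE)
  zz <- if (nk == nz) grid$z_c else grid$z_w
  if (along == "y") {
    if (index < 1 || index > nx) stop("transect index outside the domain",
                                      call. = FALSE)
    value <- field[index, , ]; depth <- zz[index, , ]
    distance <- grid$y; bottom <- grid$depth[index, ]
  } else {
    if (index < 1 || index > ny) stop("transect index outside the domain",
                                      call. = FALSE)
    value <- field[, index, ]; depth <- zz[, index, ]
    distance <- grid$x; bottom <- grid$depth[, index]
  }
  structure(list(distance = distance, depth = depth, value = value,
                 bottom = bottom, along = along, index = index),
            class = "transect_section")
}

#' Deposition versus depth by habitat class
#'
#' Joins each column's post-spinup time-mean deposition flux with its depth
#' and habitat class, and summarises coral versus off-reef deposition in
#' depth bins, including the focusing ratio (coral mean / off-reef mean) in
#' bins containing both classes.
#'
#' @param run a [integrate_scenario()] result.
#' @param grid sigma grid.
#' @param mask habitat mask.
#' @param bin_width depth bin width (m). Default 100.
#' @return list of class `deposition_analysis` with `table` (one row per
#'   column: `x`, `y`, `depth`, `habitat_class`, `deposition`) and `summary`
#'   (per depth bin: `bin_top`, `bin_mid`, `n_coral`, `n_off`,
#'   `coral_deposition`, `off_reef_deposition`, `ratio`).
#' @export
deposition_vs_depth <- function(run, grid, mask, bin_width = 100) {
  if (!is.finite(run$averaging_window) || run$averaging_window <= 0)
    stop("run contains no post-spinup samples", call. = FALSE)
  tab <- data.frame(x = rep(grid$x, times = grid$ny),
                    y = rep(grid$y, each = grid$nx),
                    depth = as.vector(grid$depth),
                    habitat_class = as.vector(mask$habitat_class),
                    deposition = as.vector(run$dep_mean_flux),
                    stringsAsFactors = FALSE)
  bin_top <- floor(tab$depth / bin_width) * bin_width
  coral <- tab$habitat_class != "off_reef"
  bins <- sort(unique(bin_top))
  summ <- do.call(rbind, lapply(bins, function(b) {
    inb <- bin_top == b
    nc <- sum(inb & coral); no <- sum(inb & !coral)
    cd <- if (nc > 0) mean(tab$deposition[inb & coral]) else NA_real_
    od <- if (no > 0) mean(tab$deposition[inb & !coral]) else NA_real_
    data.frame(bin_top = b, bin_mid = b + bin_width / 2,
               n_coral = nc, n_off = no,
               coral_deposition = cd, off_reef_deposition = od,
               ratio = if (nc > 0 && no > 0 && od > 0) cd / od else NA_real_)
  }))
  structure(list(table = tab, summary = summ, bin_width = bin_width),
            class = "deposition_analysis")
}

#' Focusing factor
#'
#' Mean of the per-bin coral / off-reef deposition ratios over all depth bins
#' that contain both habitat classes — the model's measure of how strongly
#' organic matter is routed onto coral habitat relative to the off-reef
#' seafloor at similar water depth.
#'
#' @param dep a [deposition_vs_depth()] result.
#' @return single numeric ratio (dimensionless).
#' @export
focusing_factor <- function(dep) {
  r <- dep$summary$ratio
  r <- r[is.finite(r)]
  if (length(r) == 0) stop("no depth bin contains both habitat classes",
                           call. = FALSE)
  mean(r)
}

#' Compare the three scenarios
#'
#' Per depth bin and habitat class, the deposition of each scenario plus the
#' ratios baseline / no-hydrodynamics and baseline / no-filtration.
#'
#' @param baseline,no_filtration,no_hydro `scenario_run` objects computed on
#'   the same grid and mask.
#' @param grid sigma grid.
#' @param mask habitat mask.
#' @param bin_width depth bin width (m). Default 100.
#' @return data.frame with one row per (bin, habitat class) present:
#'   `bin_top`, `bin_mid`, `habitat_class`, `n`, `baseline`, `no_filtration`,
#'   `no_hydro`, `ratio_hydro` (baseline / no_hydro), `ratio_filtration`
#'   (baseline / no_filtration).
#' @export
scenario_compare <- function(baseline, no_filtration, no_hydro, grid, mask,
                             bin_width = 100) {
  runs <- list(baseline = baseline, no_filtration = no_filtration,
               no_hydro = no_hydro)
  dims <- lapply(runs, function(r) dim(r$dep_mean_flux))
  if (!all(vapply(dims, identical, logical(1), y = dim(grid$depth))))
    stop("scenario runs are not on the same grid", call. = FALSE)
  depth <- as.vector(grid$depth)
  cls <- as.vector(mask$habitat_class)
  bin_top <- floor(depth / bin_width) * bin_width
  dep <- lapply(runs, function(r) as.vector(r$dep_mean_flux))
  keys <- unique(data.frame(bin_top = bin_top, habitat_class = cls,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$bin_top, keys$habitat_class), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- bin_top == keys$bin_top[i] & cls == keys$habitat_class[i]
    m <- vapply(dep, function(d) mean(d[sel]), numeric(1))
    data.frame(bin_top = keys$bin_top[i],
               bin_mid = keys$bin_top[i] + bin_width / 2,
               habitat_class = keys$habitat_class[i], n = sum(sel),
               baseline = m[["baseline"]],
               no_filtration = m[["no_filtration"]],
               no_hydro = m[["no_hydro"]],
               ratio_hydro = if (m[["no_hydro"]] > 0)
                 m[["baseline"]] / m[["no_hydro"]] else NA_real_,
               ratio_filtration = if (m[["no_filtration"]] > 0)
                 m[["baseline"]] / m[["no_filtration"]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot deposition versus depth
#'
#' Scatter of per-column time-mean deposition against seafloor depth,
#' colored by habitat class, on a logarithmic flux axis.
#'
#' @param x a [deposition_vs_depth()] result.
#' @param ... passed to [plot()].
#' @export
plot.deposition_analysis <- function(x, ...) {
  tab <- x$table
  cols <- c(off_reef = "grey40", coral_mound = "firebrick",
            coral_ridge = "darkorange")
  pos <- tab$deposition > 0
  graphics::plot(tab$depth[pos], tab$deposition[pos], log = "y",
                 col = cols[tab$habitat_class[pos]], pch = 16, cex = 0.6,
                 xlab = "water depth (m)",
                 ylab = expression(paste("deposition (mmol C ", m^-2, " ",
                                         d^-1, ")")), ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Plot a transect section
#'
#' Filled contour-style image of a section in distance-depth space with the
#' seafloor drawn on top.
#'
#' @param x a [transect_section()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.transect_section <- function(x, ...) {
  ord <- order(x$distance)
  graphics::image(x$distance[ord], seq_len(ncol(x$value)),
                  x$value[ord, , drop = FALSE],
                  xlab = "distance (m)", ylab = "layer", ...)
  invisible(x)
}
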