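## Buffered environmental sampling: the climate value attached to a site is
## the mean over random points in a 50-km great-circle disk around it, which
## bridges coastal sites whose exact cell may be land or sea in any one
## layer.

# Area-uniform draws in a disk of `radius_km` around (lon, lat): sqrt-uniform
# radius, uniform bearing, small-disk spherical offsets with cos(lat)
# longitude compression (sphere radius EARTH_RADIUS_KM).
disk_points <- function(lon, lat, n, radius_km) {
  theta <- stats::runif(n, 0, 2 * pi)
  d <- radius_km * sqrt(stats::runif(n))
  dlat <- (d / EARTH_RADIUS_KM) * cos(theta) * 180 / pi
  dlon <- (d / EARTH_RADIUS_KM) * sin(theta) * 180 / pi /
    cos(lat * pi / 180)
  data.frame(lon = norm_lon(lon + dlon), lat = lat + dlat)
}

#' Buffered environmental values at a point
#'
#' Samples `n_samples` points area-uniformly within a `radius_km`
#' great-circle disk of the location and returns, per variable, the mean of
#' the grid values at the samples that hit valid (non-nodata, on-grid) cells.
#'
#' @param point Data frame row or list with `lon`, `lat` (and optionally
#'   `id`, used in error messages).
#' @param grid An [env_grid()].
#' @param n_samples Number of random points (default 50).
#' @param radius_km Disk radius in km (default 50; must be > 0, but a
#'   near-zero radius degenerates to the point's own cell).
#' @param seed Integer seed; the same seed gives the same vector.
#' @param vars Variables to extract (default all layers).
#' @return Named numeric vector, one finite value per variable.
#' @export
extract_env <- function(point, grid, n_samples = 50, radius_km = 50,
                        seed = 1L, vars = names(grid$vars)) {
  stopifnot(radius_km > 0, n_samples >= 1)
  id <- if (!is.null(point$id)) point$id else
    sprintf("(%.3f, %.3f)", point$lon, point$lat)
  pts <- with_seed(seed, disk_points(point$lon, point$lat, n_samples,
                                     radius_km))
  vals <- grid_lookup(grid, pts$lon, pts$lat, vars)
  out <- colMeans(vals, na.rm = TRUE)
  if (any(is.nan(out))) {
    bad <- vars[is.nan(out)]
    stop("all ", n_samples, " samples hit nodata for variable(s) ",
         paste(bad, collapse = ", "), " at point ", id)
  }
  out
}

#' Buffered environmental values for a table of points
#'
#' Applies [extract_env()] to every row, deriving one child seed per row from
#' `seed` so results do not depend on row order of other points.
#'
#' @param points Data frame with `lon`, `lat` and optionally `id`.
#' @inheritParams extract_env
#' @return Matrix (points x variables).
#' @export
extract_env_all <- function(points, grid, n_samples = 50, radius_km = 50,
                            seed = 1L, vars = names(grid$vars)) {
  out <- matrix(NA_real_, nrow(points), length(vars),
                dimnames = list(points$id, vars))
  for (i in seq_len(nrow(points))) {
    out[i, ] <- extract_env(points[i, ], grid, n_samples, radius_km,
                            seed = child_seed(seed, paste0("pt", i)),
                            vars = vars)
  }
  out
}
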