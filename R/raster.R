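## EnvGrid: a stack of regular lat-lon rasters sharing one grid.
## Matrices are stored in ESRI ASCII row order: row 1 = northernmost row.

#' Create an environmental grid stack
#'
#' Bundles one or more climate rasters that share a regular latitude-longitude
#' grid. Cells are half-open squares `[x, x + cellsize) x [y, y + cellsize)`
#' anchored at the lower-left corner `(xll, yll)`.
#'
#' @param vars Named list of numeric matrices (same dimensions; row 1 is the
#'   northernmost row, as in ESRI ASCII files). Names are the variable names.
#' @param xll,yll Longitude/latitude of the lower-left grid corner (degrees).
#' @param cellsize Cell size in degrees (> 0).
#' @param nodata Value marking missing cells (stored as `NA` internally).
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(vars, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.list(vars), length(vars) >= 1, !is.null(names(vars)),
            cellsize > 0)
  dims <- vapply(vars, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1])) {
    stop("all layers must share one grid (equal dimensions)")
  }
  vars <- lapply(vars, function(m) {
    m[m == nodata] <- NA_real_
    m
  })
  structure(list(vars = vars, xll = xll, yll = yll, cellsize = cellsize,
                 nodata = nodata,
                 nrow = nrow(vars[[1]]), ncol = ncol(vars[[1]])),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells, %.3g deg, origin (%.3f, %.3f)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  cat("layers:", paste(names(x$vars), collapse = ", "), "\n")
  invisible(x)
}

# Cell indices (matrix row from top, column) for lon/lat vectors; NA outside.
grid_cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row_bottom <- floor((lat - grid$yll) / grid$cellsize) + 1
  row <- grid$nrow - row_bottom + 1
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Look up grid values at point locations
#'
#' @param grid An [env_grid()].
#' @param lon,lat Coordinate vectors (degrees).
#' @param vars Variables to extract (default all).
#' @return Numeric matrix, one row per point, one column per variable;
#'   `NA` for nodata cells or points outside the grid.
#' @export
grid_lookup <- function(grid, lon, lat, vars = names(grid$vars)) {
  idx <- grid_cell_index(grid, lon, lat)
  out <- matrix(NA_real_, nrow = length(lon), ncol = length(vars),
                dimnames = list(NULL, vars))
  ok <- !is.na(idx[, 1])
  for (v in vars) {
    out[ok, v] <- grid$vars[[v]][idx[ok, , drop = FALSE]]
  }
  out
}

#' Read an ESRI ASCII grid
#'
#' @param file Path to a `.asc` file.
#' @return List with `data` (matrix, row 1 = north), `xll`, `yll`,
#'   `cellsize`, `nodata`.
#' @export
read_asc <- function(file) {
  head <- readLines(file, n = 6)
  kv <- strsplit(trimws(head), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys)) stop("not an ESRI ASCII grid: ", file)
  cs <- vals[["cellsize"]]
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]] else
    vals[["xllcenter"]] - cs / 2
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]] else
    vals[["yllcenter"]] - cs / 2
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  nskip <- sum(keys %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                           "yllcorner", "yllcenter", "cellsize",
                           "nodata_value"))
  dat <- scan(file, skip = nskip, quiet = TRUE)
  m <- matrix(dat, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
              byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(data = m, xll = xll, yll = yll, cellsize = cs, nodata = nodata)
}

#' Write one layer of an environmental grid as ESRI ASCII
#'
#' @param grid An [env_grid()].
#' @param var Layer name.
#' @param file Output path.
#' @export
write_asc <- function(grid, var, file) {
  m <- grid$vars[[var]]
  if (is.null(m)) stop("no such layer: ", var)
  m[is.na(m)] <- grid$nodata
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a directory of ESRI ASCII layers as one grid stack
#'
#' Each `<var>.asc` file becomes a layer named `<var>`; all files must share
#' the same grid.
#'
#' @param dir Directory containing `.asc` files.
#' @return An [env_grid()].
#' @export
read_env_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (length(files) == 0) stop("no .asc layers in ", dir)
  layers <- lapply(files, read_asc)
  ref <- layers[[1]]
  for (l in layers[-1]) {
    if (l$xll != ref$xll || l$yll != ref$yll || l$cellsize != ref$cellsize ||
        !all(dim(l$data) == dim(ref$data))) {
      stop("layers do not share one grid")
    }
  }
  vars <- lapply(layers, `[[`, "data")
  names(vars) <- sub("\\.asc$", "", basename(files))
  env_grid(vars, ref$xll, ref$yll, ref$cellsize, ref$nodata)
}

#' Write every layer of a grid stack to a directory
#'
#' @param grid An [env_grid()].
#' @param dir Output directory (created if missing).
#' @export
write_env_dir <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in names(grid$vars)) {
    write_asc(grid, v, file.path(dir, paste0(v, ".asc")))
  }
  invisible(dir)
}
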