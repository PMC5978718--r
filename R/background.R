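## Coastal background points: centers of the grid cells that any coastline
## polyline intersects (the "available habitat" set for the ordination).

# Cells crossed by one segment, in cell units, via incremental grid
# traversal. Cells are half-open [i, i+1) x [j, j+1).
segment_cells <- function(u0, v0, u1, v1) {
  i <- floor(u0); j <- floor(v0)
  ie <- floor(u1); je <- floor(v1)
  du <- u1 - u0; dv <- v1 - v0
  out <- matrix(NA_integer_, nrow = abs(ie - i) + abs(je - j) + 1, ncol = 2)
  k <- 1L
  out[k, ] <- c(i, j)
  if (i == ie && j == je) return(out[1, , drop = FALSE])
  stepi <- sign(du); stepj <- sign(dv)
  tmaxi <- if (du > 0) (i + 1 - u0) / du else if (du < 0) (i - u0) / du else Inf
  tmaxj <- if (dv > 0) (j + 1 - v0) / dv else if (dv < 0) (j - v0) / dv else Inf
  tdi <- if (du != 0) abs(1 / du) else Inf
  tdj <- if (dv != 0) abs(1 / dv) else Inf
  while (i != ie || j != je) {
    if (tmaxi < tmaxj) {
      i <- i + stepi; tmaxi <- tmaxi + tdi
    } else {
      j <- j + stepj; tmaxj <- tmaxj + tdj
    }
    k <- k + 1L
    out[k, ] <- c(i, j)
    if (k >= nrow(out)) break
  }
  out[seq_len(k), , drop = FALSE]
}

# Split a lon pair at the antimeridian if the short arc crosses it.
split_antimeridian <- function(lon0, lat0, lon1, lat1) {
  if (abs(lon1 - lon0) <= 180) {
    return(list(c(lon0, lat0, lon1, lat1)))
  }
  # crossing: walk the short way through +/-180
  if (lon0 < lon1) { # e.g. -170 -> 170 crosses -180
    span0 <- lon0 - (-180); span1 <- 180 - lon1
    f <- span0 / (span0 + span1)
    latx <- lat0 + f * (lat1 - lat0)
    list(c(lon0, lat0, -180, latx), c(180 - 1e-9, latx, lon1, lat1))
  } else {
    span0 <- 180 - lon0; span1 <- lon1 - (-180)
    f <- span0 / (span0 + span1)
    latx <- lat0 + f * (lat1 - lat0)
    list(c(lon0, lat0, 180 - 1e-9, latx), c(-180, latx, lon1, lat1))
  }
}

#' Coastal background cell centers
#'
#' Lays a global grid of `cell_deg` x `cell_deg` half-open squares (anchored
#' at integer multiples of `cell_deg` from the origin) over the earth and
#' returns the center of every cell that any coastline polyline intersects.
#' These centers are the background ("available habitat") points of the
#' environmental ordination.
#'
#' @param coastlines A single data frame with `lon`, `lat` polyline vertices,
#'   or a (possibly named) list of such data frames.
#' @param cell_deg Cell size in degrees (default 1).
#' @return Data frame `lon`, `lat` of unique cell centers, sorted by
#'   longitude then latitude. Empty input gives an empty frame with a
#'   warning.
#' @export
build_coastal_background <- function(coastlines, cell_deg = 1.0) {
  stopifnot(cell_deg > 0)
  if (is.data.frame(coastlines)) coastlines <- list(coastlines)
  coastlines <- Filter(function(d) !is.null(d) && nrow(d) >= 1, coastlines)
  if (length(coastlines) == 0) {
    warning("no coastline polylines; empty background")
    return(data.frame(lon = numeric(0), lat = numeric(0)))
  }
  cells <- list()
  n <- 0L
  for (line in coastlines) {
    lon <- norm_lon(line$lon); lat <- line$lat
    if (nrow(line) == 1) {
      n <- n + 1L
      cells[[n]] <- cbind(floor(lon / cell_deg), floor(lat / cell_deg))
      next
    }
    for (s in seq_len(nrow(line) - 1)) {
      parts <- split_antimeridian(lon[s], lat[s], lon[s + 1], lat[s + 1])
      for (p in parts) {
        n <- n + 1L
        cells[[n]] <- segment_cells(p[1] / cell_deg, p[2] / cell_deg,
                                    p[3] / cell_deg, p[4] / cell_deg)
      }
    }
  }
  cells <- unique(do.call(rbind, cells))
  out <- data.frame(lon = (cells[, 1] + 0.5) * cell_deg,
                    lat = (cells[, 2] + 0.5) * cell_deg)
  out[order(out$lon, out$lat), , drop = FALSE]
}
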