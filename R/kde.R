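## 99% kernel-density niche regions in PCAenv space: full-covariance
## Gaussian KDE on an evaluation grid, thresholded as a highest-density
## region holding the requested mass.

#' Kernel-density niche region
#'
#' Estimates a bivariate Gaussian kernel density of the score cloud on a
#' regular evaluation grid and returns the highest-density set of cells
#' whose cumulative (grid-normalized) mass first reaches `coverage` — the
#' "99% kernel density" niche region. The bandwidth matrix is Scott's rule
#' applied to the full sample covariance, `H = n^(-1/3) * S`.
#'
#' @param scores Two-column matrix of PC scores (>= 5 points).
#' @param coverage Target mass inside the region (default 0.99).
#' @param grid_n Evaluation grid resolution per axis (default 200).
#' @param pad Grid padding beyond the data range, in marginal bandwidth
#'   units (default 3).
#' @param eval_grid Optional list `x`, `y` of cell-center coordinates to
#'   evaluate on (overrides `grid_n`/`pad`), e.g. to share a grid between
#'   regions.
#' @return Object of class `density_region`: `x`, `y` (cell centers),
#'   `density` (matrix x-by-y), `mask` (logical, inside region),
#'   `threshold` (density at the coverage boundary), `H` (bandwidth
#'   matrix), `coverage`, `n`.
#' @export
kde_region <- function(scores, coverage = 0.99, grid_n = 200, pad = 3,
                       eval_grid = NULL) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, nrow(scores) >= 5,
            coverage > 0, coverage < 1)
  n <- nrow(scores)
  S <- stats::cov(scores)
  H <- n^(-1 / 3) * S           # Scott's rule, d = 2: H = n^{-2/(d+4)} S
  # degenerate clouds (e.g. all points identical): fall back to a small
  # spherical bandwidth so the region is a compact neighborhood
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    spread <- max(apply(scores, 2, function(v) diff(range(v))), 1e-3)
    H <- diag(2) * (0.1 * spread)^2
    ev <- rep((0.1 * spread)^2, 2)
  }
  if (!all(is.finite(H))) stop("singular bandwidth matrix")
  hx <- sqrt(H[1, 1]); hy <- sqrt(H[2, 2])
  if (is.null(eval_grid)) {
    x <- seq(min(scores[, 1]) - pad * hx, max(scores[, 1]) + pad * hx,
             length.out = grid_n)
    y <- seq(min(scores[, 2]) - pad * hy, max(scores[, 2]) + pad * hy,
             length.out = grid_n)
  } else {
    x <- eval_grid$x; y <- eval_grid$y
  }

  # evaluate sum of Gaussian kernels by whitening with H^{-1/2}
  e <- eigen(H, symmetric = TRUE)
  Hinv_sqrt <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  detH <- prod(e$values)
  W <- scores %*% Hinv_sqrt                     # whitened data points
  dens <- matrix(0, length(x), length(y))
  norm_const <- 1 / (2 * pi * sqrt(detH) * n)
  chunk <- max(1L, floor(2e6 / n))
  grid_pts <- as.matrix(expand.grid(x = x, y = y))
  for (start in seq(1, nrow(grid_pts), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(grid_pts))
    G <- grid_pts[idx, , drop = FALSE] %*% Hinv_sqrt
    d2 <- outer(rowSums(G^2), rowSums(W^2), `+`) - 2 * tcrossprod(G, W)
    dens[idx] <- rowSums(exp(-0.5 * d2)) * norm_const
  }

  # highest-density region by cumulative normalized grid mass
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord]) / sum(dens)
  cut <- which(cum >= coverage)[1]
  if (is.na(cut)) cut <- length(ord)
  threshold <- dens[ord[cut]]
  mask <- dens >= threshold
  structure(list(x = x, y = y, density = dens, mask = mask,
                 threshold = threshold, H = H, coverage = coverage, n = n),
            class = "density_region")
}

# Bilinear resampling of a region's density onto a new grid, re-thresholded
# at the stored coverage boundary.
resample_region <- function(region, x, y) {
  interp <- function(xs, ys) {
    ix <- findInterval(xs, region$x, all.inside = TRUE)
    iy <- findInterval(ys, region$y, all.inside = TRUE)
    x0 <- region$x[ix]; x1 <- region$x[ix + 1]
    y0 <- region$y[iy]; y1 <- region$y[iy + 1]
    tx <- pmin(1, pmax(0, (xs - x0) / (x1 - x0)))
    ty <- pmin(1, pmax(0, (ys - y0) / (y1 - y0)))
    d <- region$density
    d[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
      d[cbind(ix + 1, iy)] * tx * (1 - ty) +
      d[cbind(ix, iy + 1)] * (1 - tx) * ty +
      d[cbind(ix + 1, iy + 1)] * tx * ty
  }
  g <- expand.grid(x = x, y = y)
  dens <- matrix(interp(g$x, g$y), length(x), length(y))
  outside <- g$x < min(region$x) | g$x > max(region$x) |
    g$y < min(region$y) | g$y > max(region$y)
  dens[outside] <- 0
  structure(list(x = x, y = y, density = dens,
                 mask = dens >= region$threshold,
                 threshold = region$threshold, H = region$H,
                 coverage = region$coverage, n = region$n),
            class = "density_region")
}

#' Fraction of points falling inside a density region
#'
#' @param region A [kde_region()] result.
#' @param scores Two-column score matrix.
#' @return Proportion of rows whose containing cell is in the region mask
#'   (points off the evaluation grid count as outside).
#' @export
region_coverage <- function(region, scores) {
  scores <- as.matrix(scores)
  mean(points_in_region(region, scores))
}

# Logical vector: is each score row inside the region mask?
points_in_region <- function(region, scores) {
  dx <- region$x[2] - region$x[1]
  dy <- region$y[2] - region$y[1]
  ix <- round((scores[, 1] - region$x[1]) / dx) + 1
  iy <- round((scores[, 2] - region$y[1]) / dy) + 1
  ok <- ix >= 1 & ix <= length(region$x) & iy >= 1 & iy <= length(region$y)
  inside <- rep(FALSE, nrow(scores))
  inside[ok] <- region$mask[cbind(ix[ok], iy[ok])]
  inside
}

#' Area of a density region
#'
#' @param region A [kde_region()] result.
#' @return Region area in squared score units (cell count x cell area).
#' @export
region_area <- function(region) {
  dx <- region$x[2] - region$x[1]
  dy <- region$y[2] - region$y[1]
  sum(region$mask) * dx * dy
}

#' @export
print.density_region <- function(x, ...) {
  cat(sprintf("<density_region> %.0f%% region, %d x %d grid, area %.3g\n",
              100 * x$coverage, length(x$x), length(x$y), region_area(x)))
  invisible(x)
}
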