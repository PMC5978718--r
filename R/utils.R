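#' @keywords internal
"_PACKAGE"

## Internal numerical / RNG helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed (global state) is restored afterwards, so no generator state
# leaks between stages.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for a named pipeline stage, kept inside the
# 32-bit integer range R's set.seed accepts.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via the
# Golub-Welsch eigen-decomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

# Mean radius of the sphere used for all great-circle work (km).
EARTH_RADIUS_KM <- 6371.0088

# Haversine great-circle distance in km between (lon1,lat1) and (lon2,lat2),
# degrees in, vectorised.
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Normalise longitudes into [-180, 180).
norm_lon <- function(lon) ((lon + 180) %% 360) - 180
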