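## Synthetic study system: meridional coastlines, latitudinal climate
## gradients, and georeferenced populations with a native-source subset.

# The 13 climate layers carried by every synthetic world.
CLIMATE_VARS <- c("SAL", "SATmax", "SATmean", "SATmin", "SATrange",
                  "SSTmax", "SSTmean", "SSTmin", "SSTrange",
                  "PREC-01", "PREC-04", "PREC-07", "PREC-10")

default_climate_table <- function() {
  # intercept at the equator, linear slope per degree |lat|, seasonality gain
  # (amplitude reached at 45 deg |lat|), cell noise sd; units degC / ppt / mm.
  tab <- data.frame(
    var = CLIMATE_VARS,
    intercept = c(33, 38, 32, 26, 12, 32, 29, 26, 4, 120, 100, 150, 110),
    slope = c(-0.05, -0.30, -0.55, -0.80, 0, -0.35, -0.45, -0.55, 0,
              -1.2, -0.8, -2.0, -1.0),
    seas_amp = c(0, 0, 0, 0, 22.5, 0, 0, 0, 11.25, 0, 0, 0, 0),
    noise_sd = c(0.5, 0.8, 0.8, 0.8, 0.8, 0.6, 0.6, 0.6, 0.6, 10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
  tab$temperature <- tab$var %in% c("SATmax", "SATmean", "SATmin",
                                    "SSTmax", "SSTmean", "SSTmin")
  tab$seasonal <- tab$var %in% c("SATrange", "SSTrange")
  tab
}

#' Configuration for a synthetic coastal world
#'
#' Describes the geometry and climate of a seeded synthetic study system:
#' a native coastline whose source subregion sits in a colder, more seasonal
#' latitude band, and three invaded coastlines shifted into warmer, less
#' seasonal climate space.
#'
#' @param seed Integer seed; all world randomness derives from it.
#' @param n_native_pops,n_source_pops Populations on the native coastline and
#'   how many of them lie in the source band (`n_source_pops <=
#'   n_native_pops`).
#' @param n_invaded_pops Named integer vector of populations per invaded
#'   coastline (defaults mirror a 5/10/10 wNA/eNA/EU sampling design).
#' @param resolution Grid cell size in degrees (> 0).
#' @param source_lat_band Latitude interval (degrees) holding the source
#'   populations.
#' @param invaded_sst_offset Warming (degrees C) added to sea/air temperature
#'   layers on invaded coastlines.
#' @param invaded_seasonality_offset Shift (degrees C) added to the seasonal
#'   range layers on invaded coastlines (negative = less seasonal).
#' @param climate Per-variable gradient table; see
#'   `nicheshift:::default_climate_table()` for the default (columns `var`,
#'   `intercept`, `slope`, `seas_amp`, `noise_sd`, `temperature`, `seasonal`).
#' @return An object of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_native_pops = 15L,
                         n_source_pops = 6L,
                         n_invaded_pops = c(wNA = 5L, eNA = 10L, EU = 10L),
                         resolution = 1,
                         source_lat_band = c(38, 44),
                         invaded_sst_offset = 3,
                         invaded_seasonality_offset = -4,
                         climate = default_climate_table()) {
  stopifnot(n_source_pops <= n_native_pops,
            resolution > 0,
            all(climate$noise_sd >= 0),
            length(source_lat_band) == 2, diff(source_lat_band) > 0,
            all(CLIMATE_VARS %in% climate$var))
  if (is.null(names(n_invaded_pops))) {
    names(n_invaded_pops) <- paste0("inv", seq_along(n_invaded_pops))
  }
  structure(list(seed = as.integer(seed),
                 n_native_pops = as.integer(n_native_pops),
                 n_source_pops = as.integer(n_source_pops),
                 n_invaded_pops = n_invaded_pops,
                 resolution = resolution,
                 source_lat_band = source_lat_band,
                 invaded_sst_offset = invaded_sst_offset,
                 invaded_seasonality_offset = invaded_seasonality_offset,
                 climate = climate),
            class = "world_config")
}

# Coastline geometry: one native meridional polyline (Japan analogue) and
# three invaded ones; invaded coastlines live west of lon 60.
world_coastlines <- function() {
  list(
    native = data.frame(lon = 141, lat = c(31, 45.5)),
    wNA = data.frame(lon = -124, lat = c(32, 49.5)),
    eNA = data.frame(lon = -76, lat = c(30, 45.5)),
    EU  = data.frame(lon = -9, lat = c(36, 58.5))
  )
}

is_invaded_lon <- function(lon) lon < 60

#' Analytic climate mean of a synthetic world
#'
#' The noiseless expectation of one climate layer at a location: intercept +
#' latitudinal slope x |lat| + seasonality amplitude x (|lat|/45), plus the
#' invaded-range offsets for temperature and seasonal-range variables.
#'
#' @param config A [world_config()].
#' @param var Climate variable name.
#' @param lon,lat Coordinates (degrees), vectorised.
#' @return Numeric vector of expected values.
#' @export
climate_mean <- function(config, var, lon, lat) {
  row <- config$climate[config$climate$var == var, ]
  if (nrow(row) != 1) stop("unknown climate variable: ", var)
  mu <- row$intercept + row$slope * abs(lat) + row$seas_amp * (abs(lat) / 45)
  inv <- is_invaded_lon(lon)
  if (row$temperature) mu <- mu + ifelse(inv, config$invaded_sst_offset, 0)
  if (row$seasonal) mu <- mu + ifelse(inv, config$invaded_seasonality_offset, 0)
  mu
}

#' Generate a synthetic coastal world
#'
#' Builds the full synthetic study system: coastline polylines, a stack of 13
#' gridded climate layers following configured latitudinal gradients, and
#' occurrence records for native (source and nonsource) and invaded
#' populations snapped to coastal cell centers. Identical configs (including
#' seed) give byte-identical worlds.
#'
#' @param config A [world_config()].
#' @return Object of class `synthetic_world`: list with `config`,
#'   `coastlines`, `grid` (an [env_grid()]) and `occurrences` (data frame
#'   `id, lon, lat, population, range_class, coastline`).
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  res <- config$resolution
  coast <- world_coastlines()

  # grid extent covers all coastlines with margin
  xll <- -135; yll <- 20
  ncol <- ceiling((150 - xll) / res)
  nrow <- ceiling((62 - yll) / res)
  cx <- xll + (seq_len(ncol) - 0.5) * res              # cell center lons
  cy <- yll + (nrow - seq_len(nrow) + 0.5) * res       # row 1 = north
  lon_m <- matrix(cx, nrow, ncol, byrow = TRUE)
  lat_m <- matrix(cy, nrow, ncol)

  vars <- list()
  for (i in seq_len(nrow(config$climate))) {
    v <- config$climate$var[i]
    mu <- matrix(climate_mean(config, v, as.vector(lon_m), as.vector(lat_m)),
                 nrow, ncol)
    sd <- config$climate$noise_sd[i]
    if (sd > 0) {
      noise <- with_seed(child_seed(config$seed, paste0("climate-", v)),
                         matrix(stats::rnorm(nrow * ncol, 0, sd), nrow, ncol))
      mu <- mu + noise
    }
    vars[[v]] <- mu
  }
  grid <- env_grid(vars, xll, yll, res)

  # coastal cells per coastline, snapped to cell centers
  occ <- list()
  for (cl in names(coast)) {
    pts <- build_coastal_background(coast[cl], cell_deg = res)
    pts <- pts[pts$lon > grid$xll & pts$lon < grid$xll + ncol * res &
               pts$lat > grid$yll & pts$lat < grid$yll + nrow * res, ]
    if (nrow(pts) == 0) stop("empty world: coastline ", cl,
                             " has no coastal cells on the grid")
    if (cl == "native") {
      in_band <- pts$lat >= config$source_lat_band[1] &
        pts$lat <= config$source_lat_band[2]
      if (sum(in_band) < config$n_source_pops ||
          sum(!in_band) < config$n_native_pops - config$n_source_pops) {
        stop("empty world: not enough coastal cells for the requested ",
             "native populations")
      }
      pick <- with_seed(child_seed(config$seed, "occ-native"), {
        src <- sample(which(in_band), config$n_source_pops)
        non <- sample(which(!in_band),
                      config$n_native_pops - config$n_source_pops)
        list(src = src, non = non)
      })
      n_src <- config$n_source_pops
      n_non <- config$n_native_pops - n_src
      occ[[cl]] <- data.frame(
        lon = pts$lon[c(pick$src, pick$non)],
        lat = pts$lat[c(pick$src, pick$non)],
        population = c(sprintf("src%02d", seq_len(n_src)),
                       sprintf("nat%02d", seq_len(n_non))),
        range_class = rep(c("native_source", "native_nonsource"),
                          c(n_src, n_non)),
        coastline = "native",
        stringsAsFactors = FALSE
      )
    } else {
      n <- config$n_invaded_pops[[cl]]
      if (nrow(pts) < n) stop("empty world: not enough coastal cells on ", cl)
      pick <- with_seed(child_seed(config$seed, paste0("occ-", cl)),
                        sample(nrow(pts), n))
      occ[[cl]] <- data.frame(
        lon = pts$lon[pick], lat = pts$lat[pick],
        population = sprintf("%s%02d", tolower(cl), seq_len(n)),
        range_class = "invaded", coastline = cl,
        stringsAsFactors = FALSE
      )
    }
  }
  occurrences <- do.call(rbind, c(occ, make.row.names = FALSE))
  occurrences <- data.frame(id = occurrences$population,
                            occurrences[, c("lon", "lat", "population",
                                            "range_class", "coastline")],
                            stringsAsFactors = FALSE)

  structure(list(config = config, coastlines = coast, grid = grid,
                 occurrences = occurrences),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed %d: %d populations (%d source) on %d coastlines\n",
              x$config$seed, nrow(x$occurrences),
              sum(x$occurrences$range_class == "native_source"),
              length(x$coastlines)))
  print(x$grid)
  invisible(x)
}

# SSTmax at each population's occurrence cell (named vector), used by the
# phenotype generator and the cline analysis.
population_sst <- function(world, var = "SSTmax") {
  occ <- world$occurrences
  v <- grid_lookup(world$grid, occ$lon, occ$lat, var)[, 1]
  tapply(v, occ$population, mean)
}
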