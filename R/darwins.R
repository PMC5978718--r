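## Rates of phenotypic evolution in darwins: one darwin is a change in a
## trait by a factor e per million years.

#' Darwin rate of phenotypic change
#'
#' `|ln(x2 / x1)| / (years / 1e6)`: the magnitude of proportional trait
#' change per million years. Symmetric in the two trait values and invariant
#' to common rescaling.
#'
#' @param x1,x2 Positive trait values at the two time points (same units).
#' @param years Elapsed time in years (> 0).
#' @return Rate in darwins (>= 0), vectorised.
#' @export
darwin_rate <- function(x1, x2, years) {
  if (any(x1 <= 0) || any(x2 <= 0) || any(years <= 0)) {
    stop("darwin_rate requires positive trait values and elapsed time")
  }
  abs(log(x2 / x1)) / (years / 1e6)
}

#' Average darwin rates over coastline x treatment cells
#'
#' @param rates Data frame with `stressor` and `rate` columns (one row per
#'   coastline x treatment-level cell), or a bare numeric vector.
#' @return Named numeric vector: arithmetic mean rate per stressor (or a
#'   single mean for a bare vector).
#' @export
rate_summary <- function(rates) {
  if (is.numeric(rates)) {
    if (length(rates) == 0) stop("no rate estimates")
    return(mean(rates))
  }
  if (nrow(rates) == 0) stop("no rate estimates")
  vapply(split(rates$rate, rates$stressor), mean, numeric(1))
}

#' Darwin rates from bleaching assays
#'
#' For every stressor x invaded coastline x treatment level, takes the
#' native-source and invaded-coastline mean "proportion bleached" (floored
#' at `epsilon` so ratios stay defined) as the trait values at the start and
#' end of the invasion window and converts them to darwins; per-stressor
#' rates average across the coastline x level cells.
#'
#' @param assays Assay data frame (see [make_phenotypes()]).
#' @param years Invasion timescale in years (default 100).
#' @param epsilon Floor for the proportion-bleached trait (default 0.01).
#' @param stage Assay stage to use (default `"field"`).
#' @param native_class Range class giving the pre-invasion trait.
#' @return List `cells` (data frame `stressor`, `coastline`, `level`,
#'   `trait_native`, `trait_invaded`, `rate`) and `summary` (mean darwins
#'   per stressor).
#' @export
darwin_rates <- function(assays, years = 100, epsilon = 0.01,
                         stage = "field", native_class = "native_source") {
  d <- assays[assays$stage == stage, , drop = FALSE]
  if (nrow(d) == 0) stop("no assay rows for stage ", stage)
  coastlines <- sort(unique(d$coastline[d$range_class == "invaded"]))
  cells <- list(); k <- 0L
  for (s in unique(d$stressor)) {
    ds <- d[d$stressor == s, , drop = FALSE]
    for (lv in unique(ds$level)) {
      dl <- ds[ds$level == lv, , drop = FALSE]
      nat <- dl$sbs[dl$range_class == native_class]
      if (length(nat) == 0) next
      x1 <- max(proportion_bleached(nat), epsilon)
      for (cl in coastlines) {
        inv <- dl$sbs[dl$coastline == cl & dl$range_class == "invaded"]
        if (length(inv) == 0) next
        x2 <- max(proportion_bleached(inv), epsilon)
        k <- k + 1L
        cells[[k]] <- data.frame(stressor = s, coastline = cl, level = lv,
                                 trait_native = x1, trait_invaded = x2,
                                 rate = darwin_rate(x1, x2, years),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  if (is.null(cells)) stop("no coastline x level cells with data")
  list(cells = cells, summary = rate_summary(cells))
}
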