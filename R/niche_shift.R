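## End-to-end niche-shift analysis: background sampling -> buffered
## environmental extraction -> correlation filter -> PCAenv -> 99% kernel
## density regions -> O/E/U classification and centroid shift.

#' Genetically informed niche-shift analysis
#'
#' Runs the full ordination workflow: build coastal background points, take
#' buffered environmental averages for background and occurrence sites, drop
#' highly correlated variables, fit the PCAenv, delimit the 99%
#' kernel-density regions of the native (all-native or source-only) and
#' invaded occurrence scores on a shared evaluation grid, and classify niche
#' cells and populations as Overlap / Expansion / Unfilled.
#'
#' @param occurrences Data frame `id, lon, lat, population, range_class,
#'   coastline`.
#' @param coastlines List of coastline polyline data frames (`lon`, `lat`).
#' @param grid An [env_grid()] with the climate layers.
#' @param source_only Restrict the native niche to genetically identified
#'   source populations (`range_class == "native_source"`; the genetically
#'   informed comparison). `FALSE` uses the whole native range.
#' @param coverage Kernel-density mass defining the niche regions (default
#'   0.99).
#' @param cell_deg Background cell size in degrees.
#' @param n_samples,radius_km Buffered-extraction settings (see
#'   [extract_env()]).
#' @param cor_threshold Correlation filter threshold.
#' @param grid_n Kernel-density evaluation resolution.
#' @param seed Integer seed for the buffered sampling.
#' @return Object of class `niche_shift`: `retained_vars`, `pca`,
#'   `background` (points), `regions` (native, invaded), `classification`
#'   (a [classify_niche()] result), `centroid_shift`, `scores` (per
#'   occurrence record), `source_only`.
#' @export
niche_shift <- function(occurrences, coastlines, grid, source_only = TRUE,
                        coverage = 0.99, cell_deg = 1.0, n_samples = 50,
                        radius_km = 50, cor_threshold = 0.9, grid_n = 200,
                        seed = 1L) {
  stopifnot(all(c("id", "lon", "lat", "population", "range_class") %in%
                  names(occurrences)))
  bg <- build_coastal_background(coastlines, cell_deg = cell_deg)
  xmax <- grid$xll + grid$ncol * grid$cellsize
  ymax <- grid$yll + grid$nrow * grid$cellsize
  bg <- bg[bg$lon >= grid$xll & bg$lon <= xmax &
             bg$lat >= grid$yll & bg$lat <= ymax, , drop = FALSE]
  if (nrow(bg) == 0) stop("no background cells on the environmental grid")

  env_bg <- extract_env_all(bg, grid, n_samples, radius_km,
                            seed = child_seed(seed, "bg"))
  env_occ <- extract_env_all(occurrences, grid, n_samples, radius_km,
                             seed = child_seed(seed, "occ"))
  retained <- filter_correlated(rbind(env_bg, env_occ), cor_threshold)
  pca <- fit_pcaenv(env_bg[, retained, drop = FALSE],
                    env_occ[, retained, drop = FALSE])
  sc <- pca$scores_occurrences[, 1:2, drop = FALSE]

  native_classes <- if (source_only) "native_source" else
    c("native_source", "native_nonsource")
  nat <- sc[occurrences$range_class %in% native_classes, , drop = FALSE]
  inv <- sc[occurrences$range_class == "invaded", , drop = FALSE]
  if (nrow(nat) < 5 || nrow(inv) < 5) {
    stop("need >= 5 native and invaded occurrence records for the ",
         "kernel density regions")
  }

  # shared evaluation grid spanning both clouds
  all_sc <- rbind(nat, inv)
  padx <- 3 * stats::sd(all_sc[, 1]); pady <- 3 * stats::sd(all_sc[, 2])
  eval_grid <- list(
    x = seq(min(all_sc[, 1]) - padx, max(all_sc[, 1]) + padx,
            length.out = grid_n),
    y = seq(min(all_sc[, 2]) - pady, max(all_sc[, 2]) + pady,
            length.out = grid_n))
  region_nat <- kde_region(nat, coverage, eval_grid = eval_grid)
  region_inv <- kde_region(inv, coverage, eval_grid = eval_grid)

  pops <- population_scores(sc, occurrences$population)
  cls <- classify_niche(region_nat, region_inv, pops)
  shift <- centroid_shift(nat, inv)

  scores <- data.frame(occurrences[, c("id", "population", "range_class")],
                       PC1 = sc[, 1], PC2 = sc[, 2],
                       stringsAsFactors = FALSE)
  structure(list(retained_vars = retained, pca = pca, background = bg,
                 regions = list(native = region_nat, invaded = region_inv),
                 classification = cls, centroid_shift = shift,
                 scores = scores, source_only = source_only),
            class = "niche_shift")
}

#' @export
print.niche_shift <- function(x, ...) {
  cat("<niche_shift>", if (x$source_only) "(source-only native niche)"
      else "(all-native niche)", "\n")
  cat("retained variables:", paste(x$retained_vars, collapse = ", "), "\n")
  cat(sprintf("PC1 + PC2 explain %.1f%% of variance\n",
              100 * sum(x$pca$var_frac[1:2])))
  cat(sprintf("centroid shift: dPC1 = %.3f, dPC2 = %.3f\n",
              x$centroid_shift[1], x$centroid_shift[2]))
  print(x$classification)
  invisible(x)
}
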