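## Overlap / Expansion / Unfilled classification: set algebra on the
## native-source and invaded 99% kernel-density niche regions, plus the
## centroid shift of realized niche space.

#' Classify niche space and populations as Overlap / Expansion / Unfilled
#'
#' Labels every cell of the shared evaluation grid by set algebra on the two
#' region masks — `O` (both), `E` (invaded only), `U` (native only),
#' `outside` (neither) — and labels each population by the cell containing
#' its score. When the native side is restricted to genetically identified
#' source populations this is the genetically informed niche-shift
#' classification.
#'
#' @param native_region [kde_region()] of native (or native-source)
#'   occurrence scores.
#' @param invaded_region [kde_region()] of invaded occurrence scores. If its
#'   evaluation grid differs it is resampled onto the native grid (set
#'   `resample = FALSE` to error instead).
#' @param pop_scores Data frame with `population`, `PC1`, `PC2` (one row per
#'   population; see [population_scores()]).
#' @param resample Allow resampling of a mismatched invaded grid.
#' @return Object of class `niche_classification`: `x`, `y`, `cells` (factor
#'   matrix of labels), `populations` (data frame with `label` column), and
#'   the two masks.
#' @export
classify_niche <- function(native_region, invaded_region, pop_scores,
                           resample = TRUE) {
  if (!isTRUE(all.equal(native_region$x, invaded_region$x)) ||
      !isTRUE(all.equal(native_region$y, invaded_region$y))) {
    if (!resample) stop("evaluation grids differ and resampling is disabled")
    invaded_region <- resample_region(invaded_region,
                                      native_region$x, native_region$y)
  }
  nm <- native_region$mask
  im <- invaded_region$mask
  lab <- matrix("outside", nrow(nm), ncol(nm))
  lab[nm & im] <- "O"
  lab[im & !nm] <- "E"
  lab[nm & !im] <- "U"
  cells <- matrix(factor(lab, levels = c("O", "E", "U", "outside")),
                  nrow(nm), ncol(nm))

  pops <- pop_scores
  sc <- as.matrix(pops[, c("PC1", "PC2")])
  in_nat <- points_in_region(native_region, sc)
  in_inv <- points_in_region(invaded_region, sc)
  pops$label <- ifelse(in_nat & in_inv, "O",
                       ifelse(in_inv, "E", ifelse(in_nat, "U", "outside")))
  structure(list(x = native_region$x, y = native_region$y, cells = cells,
                 native_mask = nm, invaded_mask = im,
                 populations = pops),
            class = "niche_classification")
}

#' @export
print.niche_classification <- function(x, ...) {
  cat("<niche_classification>\n")
  cat("cells:", paste(names(table(x$cells)), table(x$cells),
                      sep = "=", collapse = ", "), "\n")
  cat("populations:", paste(names(table(x$populations$label)),
                            table(x$populations$label),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-population mean scores in niche space
#'
#' Populations with several occurrence records are placed at the mean of
#' their member-occurrence scores.
#'
#' @param scores Two-column score matrix for occurrence records.
#' @param population Population code per occurrence record.
#' @return Data frame `population`, `PC1`, `PC2`.
#' @export
population_scores <- function(scores, population) {
  scores <- as.matrix(scores)
  p1 <- tapply(scores[, 1], population, mean)
  p2 <- tapply(scores[, 2], population, mean)
  data.frame(population = names(p1), PC1 = as.numeric(p1),
             PC2 = as.numeric(p2), stringsAsFactors = FALSE)
}

#' Centroid shift of realized niche space
#'
#' Difference of the arithmetic mean scores, invaded minus native — the
#' arrow drawn between range centroids in niche space.
#'
#' @param native_scores,invaded_scores Two-column score matrices (nonempty).
#' @return Named numeric vector `dPC1`, `dPC2`.
#' @export
centroid_shift <- function(native_scores, invaded_scores) {
  native_scores <- as.matrix(native_scores)
  invaded_scores <- as.matrix(invaded_scores)
  if (nrow(native_scores) == 0 || nrow(invaded_scores) == 0) {
    stop("centroid_shift: empty score set")
  }
  d <- colMeans(invaded_scores[, 1:2, drop = FALSE]) -
    colMeans(native_scores[, 1:2, drop = FALSE])
  stats::setNames(as.numeric(d), c("dPC1", "dPC2"))
}
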