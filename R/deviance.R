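## The ordinal-regression battery: analysis-of-deviance tables for region x
## treatment effects on SBS, the Overlap-vs-Expansion niche contrast, and
## the ANCOVA-like sea-surface-temperature cline models.

# Subset assay rows for one stressor/stage and build the region factor
# (native source = reference level vs a chosen non-native set).
assay_subset <- function(assays, stressor, stage,
                         native_class = "native_source",
                         nonnative = NULL) {
  d <- assays[assays$stressor == stressor & assays$stage == stage, ,
              drop = FALSE]
  is_nat <- d$range_class == native_class
  is_non <- d$range_class == "invaded" &
    (if (is.null(nonnative)) TRUE else d$coastline %in% nonnative)
  d <- d[is_nat | is_non, , drop = FALSE]
  d$region <- factor(ifelse(d$range_class == native_class,
                            "native", "nonnative"),
                     levels = c("native", "nonnative"))
  d$level <- factor(d$level, levels = unique(assays$level[
    assays$stressor == stressor]))
  d$level <- droplevels(d$level)
  d
}

sample_sizes <- function(d) {
  do.call(rbind, lapply(split(d, d$region), function(r) data.frame(
    region = r$region[1],
    thalli = length(unique(r$thallus)),
    populations = length(unique(r$population)))))
}

fit_ordinal <- function(y, X, group, use_re, nodes = 15) {
  if (use_re) fit_clmm(y, X, group, nodes = nodes) else fit_clm(y, X)
}

#' Analysis-of-deviance table for region and treatment effects on SBS
#'
#' Fits the full proportional-odds model `SBS ~ region * treatment` with a
#' population random intercept and derives likelihood-ratio rows: the random
#' intercept (mixed vs fixed-effects full model), the overall model
#' (intercept-only vs full), and region, treatment and interaction (each
#' term's columns dropped from the full design). Post hoc rows test the
#' region effect within each treatment level separately. Raw p-values are
#' reported (no multiplicity correction).
#'
#' @param assays Assay data frame from [make_phenotypes()] (or same layout:
#'   `population`, `range_class`, `coastline`, `stressor`, `level`, `stage`,
#'   `sbs`).
#' @param stressor,stage Assay subset to analyse.
#' @param native_class Range class treated as the native source reference.
#' @param nonnative Optional coastline subset for the non-native side
#'   (default: all invaded populations).
#' @param posthoc_re Use the population random intercept in per-level post
#'   hoc refits (default TRUE).
#' @param nodes Quadrature nodes for the mixed fits.
#' @return Object of class `deviance_table`: data frame `term`, `df`,
#'   `statistic`, `p`, with sample sizes (thalli, populations per region) as
#'   attribute `sizes`.
#' @export
deviance_table <- function(assays, stressor, stage = "field",
                           native_class = "native_source", nonnative = NULL,
                           posthoc_re = TRUE, nodes = 15) {
  d <- assay_subset(assays, stressor, stage, native_class, nonnative)
  if (nrow(d) == 0) stop("no assay rows for ", stressor, "/", stage)
  if (nlevels(d$level) < 2) stop("need >= 2 treatment levels")
  sizes <- sample_sizes(d)
  row_na <- function(term, df) data.frame(term = term, df = df,
                                          statistic = NA_real_, p = NA_real_)
  if (any(table(d$region) == 0)) {
    warning("a region has zero thalli; contrasts not estimable")
    out <- rbind(row_na("(1 | population)", 1), row_na("overall", NA),
                 row_na("region", NA), row_na("treatment", NA),
                 row_na("interaction", NA))
    return(structure(out, sizes = sizes, class = c("deviance_table",
                                                   "data.frame")))
  }

  pops_per_region <- tapply(d$population, d$region,
                            function(p) length(unique(p)))
  re_ok <- all(pops_per_region >= 2)
  use_re <- re_ok

  y <- d$sbs
  mm <- stats::model.matrix(~ region * level, data = d)
  asn <- attr(mm, "assign")
  X_full <- mm[, asn != 0, drop = FALSE]
  asn <- asn[asn != 0]

  full <- fit_ordinal(y, X_full, d$population, use_re, nodes)
  rows <- list()

  # random-intercept row: mixed vs fixed full model (1 df, no boundary
  # correction); not estimable when a region holds a single population
  if (re_ok) {
    fixed_full <- fit_clm(y, X_full)
    t <- lrt(fixed_full, full)
    rows$re <- data.frame(term = "(1 | population)", df = t$df,
                          statistic = t$statistic, p = t$p)
  } else {
    rows$re <- row_na("(1 | population)", 1)
  }

  null0 <- fit_ordinal(y, NULL, d$population, use_re, nodes)
  t <- lrt(null0, full)
  rows$overall <- data.frame(term = "overall", df = t$df,
                             statistic = t$statistic, p = t$p)
  for (term in list(c("region", 1), c("treatment", 2), c("interaction", 3))) {
    keep <- asn != as.integer(term[2])
    red <- fit_ordinal(y, X_full[, keep, drop = FALSE], d$population,
                       use_re, nodes)
    t <- lrt(red, full)
    rows[[term[1]]] <- data.frame(term = term[1], df = t$df,
                                  statistic = t$statistic, p = t$p)
  }

  # post hoc: region effect within each treatment level
  for (lv in levels(d$level)) {
    dl <- d[d$level == lv, , drop = FALSE]
    if (any(table(dl$region) == 0)) {
      rows[[paste0("ph_", lv)]] <- row_na(paste0("posthoc:", lv), 1)
      next
    }
    re_lv <- posthoc_re &&
      all(tapply(dl$population, dl$region,
                 function(p) length(unique(p))) >= 2)
    Xl <- stats::model.matrix(~ region, data = dl)[, -1, drop = FALSE]
    f1 <- fit_ordinal(dl$sbs, Xl, dl$population, re_lv, nodes)
    f0 <- fit_ordinal(dl$sbs, NULL, dl$population, re_lv, nodes)
    t <- lrt(f0, f1)
    rows[[paste0("ph_", lv)]] <- data.frame(term = paste0("posthoc:", lv),
                                            df = t$df,
                                            statistic = t$statistic, p = t$p)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(out, sizes = sizes, stressor = stressor, stage = stage,
            class = c("deviance_table", "data.frame"))
}

#' @export
print.deviance_table <- function(x, ...) {
  cat("Analysis of deviance",
      if (!is.null(attr(x, "stressor")))
        paste0("(", attr(x, "stressor"), ", ", attr(x, "stage"), ")"), "\n")
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  s <- attr(x, "sizes")
  if (!is.null(s)) {
    cat("sample sizes:",
        paste(sprintf("%s %d (%d)", s$region, s$thalli, s$populations),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Overlap-versus-Expansion phenotype contrast
#'
#' Tests whether populations in Expansion niche space differ in bleaching
#' response from populations in Overlap niche space: proportional-odds
#' regression of SBS on the O/E label with a population random intercept,
#' after dropping any excluded populations (e.g. coastlines whose thalli are
#' not fully traced to the genetic source).
#'
#' @param assays Assay data frame (see [deviance_table()]).
#' @param labels Data frame `population`, `label` (from
#'   [classify_niche()]`$populations`); only `O`/`E` rows are used.
#' @param exclude Population codes to drop before fitting.
#' @param stressor,stage Assay subset.
#' @param level Optional single treatment level (default: all levels of the
#'   stressor pooled).
#' @param nodes Quadrature nodes.
#' @return List `fit` (the mixed fit), `p` (likelihood-ratio p for the O/E
#'   effect), `means` (mean SBS per group), `n` (thalli per group).
#' @export
ove_contrast <- function(assays, labels, exclude = character(),
                         stressor = "heat40", stage = "field", level = NULL,
                         nodes = 15) {
  lab <- labels[labels$label %in% c("O", "E") &
                  !(labels$population %in% exclude), , drop = FALSE]
  d <- assays[assays$stressor == stressor & assays$stage == stage &
                assays$population %in% lab$population, , drop = FALSE]
  if (!is.null(level)) d <- d[d$level == level, , drop = FALSE]
  d$niche <- factor(lab$label[match(d$population, lab$population)],
                    levels = c("O", "E"))
  if (any(table(d$niche) == 0)) {
    stop("one of the O/E groups is empty after exclusions")
  }
  use_re <- all(tapply(d$population, d$niche,
                       function(p) length(unique(p))) >= 2)
  X <- stats::model.matrix(~ niche, data = d)[, -1, drop = FALSE]
  f1 <- fit_ordinal(d$sbs, X, d$population, use_re, nodes)
  f0 <- fit_ordinal(d$sbs, NULL, d$population, use_re, nodes)
  t <- lrt(f0, f1)
  list(fit = f1, p = t$p,
       means = tapply(d$sbs, d$niche, mean),
       n = table(d$niche))
}

#' Sea-surface-temperature cline model for heat tolerance
#'
#' ANCOVA-like proportional-odds regression of SBS on population SSTmax,
#' region and their interaction, with a population random intercept —
#' testing whether tolerance clines along the thermal gradient run in
#' parallel across a native and a non-native coastline. Also returns
#' per-region predicted bleaching-probability curves over the SST range and,
#' when occurrences are supplied, the R-squared of SSTmax against |latitude|
#' per coastline as a gradient diagnostic.
#'
#' @param assays Assay data frame.
#' @param sst Named vector: SSTmax per population (e.g. from
#'   `nicheshift:::population_sst()` or extracted rasters).
#' @param coastlines Length-2 character: native-side and non-native-side
#'   coastline codes (native first; it becomes the reference level).
#' @param stressor,level,stage Assay subset (one treatment level, as in the
#'   per-level cline tables).
#' @param occurrences Optional occurrence table with `lat`, `population`,
#'   `coastline` for the SST-latitude diagnostic.
#' @param nodes Quadrature nodes.
#' @return List `table` (deviance rows: random intercept, overall, region,
#'   SST, interaction), `fit`, `curves` (region, sst, p_bleached),
#'   `sst_lat_r2` (named vector or NULL), `slopes` (per-region latent SST
#'   slopes).
#' @export
cline_model <- function(assays, sst, coastlines, stressor = "heat40",
                        level, stage = "field", occurrences = NULL,
                        nodes = 15) {
  stopifnot(length(coastlines) == 2)
  d <- assays[assays$stressor == stressor & assays$stage == stage &
                assays$level == level &
                assays$coastline %in% coastlines, , drop = FALSE]
  if (nrow(d) == 0) stop("no assay rows for the requested cline subset")
  d$region <- factor(d$coastline, levels = coastlines)
  d$sst <- as.numeric(sst[d$population])
  if (any(is.na(d$sst))) stop("missing SSTmax for some populations")
  within_var <- tapply(d$sst, d$region, stats::var)
  if (all(within_var < 1e-12)) {
    stop("SST constant within both regions; slope not estimable")
  }
  sst_center <- mean(d$sst)
  d$sst_c <- d$sst - sst_center

  mm <- stats::model.matrix(~ sst_c * region, data = d)
  asn <- attr(mm, "assign")
  X_full <- mm[, asn != 0, drop = FALSE]
  asn <- asn[asn != 0]
  use_re <- all(tapply(d$population, d$region,
                       function(p) length(unique(p))) >= 2)
  full <- fit_ordinal(d$sbs, X_full, d$population, use_re, nodes)

  rows <- list()
  if (use_re) {
    t <- lrt(fit_clm(d$sbs, X_full), full)
    rows$re <- data.frame(term = "(1 | population)", df = t$df,
                          statistic = t$statistic, p = t$p)
  } else {
    rows$re <- data.frame(term = "(1 | population)", df = 1,
                          statistic = NA_real_, p = NA_real_)
  }
  t <- lrt(fit_ordinal(d$sbs, NULL, d$population, use_re, nodes), full)
  rows$overall <- data.frame(term = "overall", df = t$df,
                             statistic = t$statistic, p = t$p)
  for (term in list(c("SST", 1), c("region", 2), c("interaction", 3))) {
    keep <- asn != as.integer(term[2])
    red <- fit_ordinal(d$sbs, X_full[, keep, drop = FALSE], d$population,
                       use_re, nodes)
    t <- lrt(red, full)
    rows[[term[1]]] <- data.frame(term = term[1], df = t$df,
                                  statistic = t$statistic, p = t$p)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))

  # predicted bleaching probability P(SBS > 0) at random intercept 0
  grid <- seq(min(d$sst), max(d$sst), length.out = 50)
  n_le0 <- sum(as.numeric(full$levels) <= 0)  # categories at or below SBS 0
  K <- length(full$levels)
  curves <- do.call(rbind, lapply(coastlines, function(cl) {
    nd <- data.frame(sst_c = grid - sst_center,
                     region = factor(cl, levels = coastlines))
    Xn <- stats::model.matrix(~ sst_c * region, data = nd)[, -1, drop = FALSE]
    eta <- drop(Xn %*% full$beta)
    p_ble <- if (n_le0 == 0) rep(1, length(eta)) else
      if (n_le0 >= K) rep(0, length(eta)) else
        1 - stats::plogis(full$theta[n_le0] - eta)
    data.frame(region = cl, sst = grid, p_bleached = p_ble)
  }))

  r2 <- NULL
  if (!is.null(occurrences)) {
    r2 <- vapply(unique(occurrences$coastline), function(cl) {
      o <- occurrences[occurrences$coastline == cl, , drop = FALSE]
      s <- sst[o$population]
      if (length(s) < 3 || stats::var(abs(o$lat)) == 0) return(NA_real_)
      summary(stats::lm(s ~ abs(o$lat)))$r.squared
    }, numeric(1))
  }

  b <- full$beta
  slope_native <- unname(b["sst_c"])
  inter <- b[grepl(":", names(b))]
  slope_non <- slope_native + if (length(inter)) unname(inter[1]) else 0
  list(table = structure(tab, class = c("deviance_table", "data.frame"),
                         sizes = sample_sizes(d)),
       fit = full, curves = curves, sst_lat_r2 = r2,
       slopes = c(native = slope_native, nonnative = slope_non))
}
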