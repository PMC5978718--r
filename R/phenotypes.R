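## Synthetic ordinal bleaching assays from a latent proportional-odds model:
## population random intercepts, a region tolerance effect, an SST-linked
## cline, and stressor severities entering the latent mean linearly.

# Stressor levels and their printed units, mirroring a heat / cold / low-
# salinity assay design (1/2/4 hr at 40C; 45/75/105 min at -20C; 0/5/10 ppt).
default_severities <- function() {
  list(heat40 = c("1hr" = 1.5, "2hr" = 2.5, "4hr" = 3.5),
       coldm20 = c("45min" = 1.2, "75min" = 2.2, "105min" = 3.2),
       salinity = c("0ppt" = 3.0, "5ppt" = 2.2, "10ppt" = 1.4))
}

#' Parameters for the ordinal phenotype generator
#'
#' Latent-scale parameters of the cumulative-logit model the generator draws
#' from: `P(BS <= k) = logistic(cutpoint_k - eta)` with
#' `eta = u_pop + beta_region x invaded + beta_sst x centered SSTmax +
#' severity`.
#'
#' @param cutpoints Strictly increasing latent cutpoints (length K-1 for K
#'   ordinal categories; default two cutpoints for scores 1/2/3, placed so
#'   control bleaching is rare).
#' @param beta_region Latent shift for invaded-range populations (negative =
#'   more tolerant, less bleaching).
#' @param beta_sst Latent slope per degree C of population SSTmax (negative =
#'   warmer-site populations more tolerant).
#' @param sigma_pop Population random-intercept standard deviation (>= 0).
#' @param severities Named list per stressor of named severity vectors
#'   (latent units per treatment level); controls are severity 0.
#' @param thalli_per_pop Thalli assayed per population.
#' @return Object of class `pheno_sim_params`.
#' @export
pheno_sim_params <- function(cutpoints = c(2.2, 4.0),
                             beta_region = -1.5,
                             beta_sst = -0.2,
                             sigma_pop = 0.5,
                             severities = default_severities(),
                             thalli_per_pop = 16L) {
  if (any(diff(cutpoints) <= 0)) stop("cutpoints must be strictly increasing")
  stopifnot(sigma_pop >= 0, thalli_per_pop >= 0, length(cutpoints) >= 1)
  structure(list(cutpoints = cutpoints, beta_region = beta_region,
                 beta_sst = beta_sst, sigma_pop = sigma_pop,
                 severities = severities,
                 thalli_per_pop = as.integer(thalli_per_pop)),
            class = "pheno_sim_params")
}

# Category probabilities of the cumulative-logit model at latent mean eta.
clm_probs <- function(cutpoints, eta) {
  cum <- vapply(cutpoints, function(th) stats::plogis(th - eta),
                numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  cbind(cum, 1)[, c(1, seq_len(ncol(cum)) + 1), drop = FALSE] -
    cbind(0, cum)
}

draw_ordinal <- function(cutpoints, eta) {
  u <- stats::runif(length(eta))
  cum <- vapply(cutpoints, function(th) stats::plogis(th - eta),
                numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  1L + rowSums(u > cum)
}

#' Generate synthetic ordinal bleaching assays
#'
#' Draws per-thallus Bleaching Scores (1 = none, 2 = partial, 3 = full) under
#' control and three-level stress treatments from the latent cumulative-logit
#' model in [pheno_sim_params()], and returns them with the Standardized
#' Bleach Score `SBS = BS_treatment - BS_control`.
#'
#' @param world A [make_world()] result (supplies populations, range classes
#'   and per-population SSTmax).
#' @param params A [pheno_sim_params()].
#' @param seed Integer seed.
#' @param stressors Which stressors to assay (default all configured).
#' @param stage Assay stage label (`"field"` or `"common_garden"`).
#' @param pop_effects Optional named latent offsets per population (e.g. a
#'   planted tolerance advantage for niche-expansion populations).
#' @return Data frame `thallus, population, coastline, range_class, stressor,
#'   level, stage, bs_control, bs_treatment, sbs`.
#' @export
make_phenotypes <- function(world, params = pheno_sim_params(), seed = 1L,
                            stressors = names(params$severities),
                            stage = "field", pop_effects = NULL) {
  stopifnot(inherits(params, "pheno_sim_params"))
  occ <- world$occurrences
  pops <- unique(occ$population)
  empty <- data.frame(thallus = character(0), population = character(0),
                      coastline = character(0), range_class = character(0),
                      stressor = character(0), level = character(0),
                      stage = character(0), bs_control = integer(0),
                      bs_treatment = integer(0), sbs = integer(0))
  if (params$thalli_per_pop == 0 || length(pops) == 0) return(empty)

  sst <- population_sst(world)
  sst_c <- sst - mean(sst)
  cls <- occ$range_class[match(pops, occ$population)]
  coastl <- occ$coastline[match(pops, occ$population)]
  offs <- if (is.null(pop_effects)) rep(0, length(pops)) else {
    o <- pop_effects[pops]
    o[is.na(o)] <- 0
    as.numeric(o)
  }

  with_seed(child_seed(seed, "phenotypes"), {
    u <- stats::rnorm(length(pops), 0, params$sigma_pop)
    base_eta <- u + params$beta_region * (cls == "invaded") +
      params$beta_sst * sst_c[pops] + offs
    out <- list(); k <- 0L
    nt <- params$thalli_per_pop
    for (p in seq_along(pops)) {
      for (s in stressors) {
        sev <- params$severities[[s]]
        bs_ctrl <- draw_ordinal(params$cutpoints, rep(base_eta[p], nt))
        for (lv in names(sev)) {
          bs_trt <- draw_ordinal(params$cutpoints,
                                 rep(base_eta[p] + sev[[lv]], nt))
          k <- k + 1L
          out[[k]] <- data.frame(
            thallus = sprintf("%s-t%02d", pops[p], seq_len(nt)),
            population = pops[p], coastline = coastl[p],
            range_class = cls[p], stressor = s, level = lv, stage = stage,
            bs_control = bs_ctrl, bs_treatment = bs_trt,
            sbs = bs_trt - bs_ctrl, stringsAsFactors = FALSE)
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
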