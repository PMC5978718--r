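## One-seed orchestration of the whole analysis: simulate -> niche shift ->
## clone filter -> ordinal phenotype statistics -> darwin rates, with every
## stage's outputs written under one run directory and a JSON manifest.

#' Default pipeline configuration
#'
#' @param seed Global seed; each stochastic stage derives a child seed from
#'   it.
#' @param outdir Run directory for outputs.
#' @param ... Overrides for any default entry (`coverage`, `alpha`, `nodes`,
#'   `years`, `epsilon`, `source_only`, `contrast_stressor`,
#'   `cline_coastlines`, `cline_level`, `exclude_populations`, plus
#'   `world`, `geno`, `pheno` parameter lists passed to the generators).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("nicheshift-run"), ...) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              coverage = 0.99, alpha = 0.05, nodes = 15,
              years = 100, epsilon = 0.01, source_only = TRUE,
              contrast_stressor = "heat40",
              cline_coastlines = c("native", "eNA"),
              cline_level = "4hr",
              exclude_populations = character(0),
              world = list(), geno = list(), pheno = list())
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a flat YAML file
#'
#' @param path YAML file with the [run_config()] keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

write_csv0 <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: world/genotype/phenotype simulation, the
#' genetically informed niche-shift classification, clone and haploid
#' filtering, the ordinal phenotype battery (per-stressor analysis-of-
#' deviance tables, the Overlap-vs-Expansion contrast, the SST cline model)
#' on the filtered thalli, and darwin-rate estimation. All outputs and a
#' manifest are written under `config$outdir`.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @return The report list (invisibly written as `report.json`): niche
#'   labels, centroid shift, deviance tables, O-vs-E contrast, cline fit,
#'   darwin rates, seed and file inventory.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  files <- character(0)

  ## stage 1: simulate
  wc <- do.call(world_config, c(list(seed = child_seed(config$seed, "world")),
                                config$world))
  world <- make_world(wc)
  gp <- do.call(geno_sim_params, config$geno)
  geno <- make_genotypes(world, gp, seed = child_seed(config$seed, "geno"))
  pp <- do.call(pheno_sim_params, config$pheno)
  pheno <- make_phenotypes(world, pp, seed = child_seed(config$seed, "pheno"))
  files <- c(files,
             write_csv0(world$occurrences, out("occurrences.csv")),
             write_csv0(geno$genotypes, out("genotypes.csv")),
             write_csv0(geno$truth, out("genotype_truth.csv")),
             write_csv0(pheno, out("phenotypes.csv")))
  write_env_dir(world$grid, out("env"))

  ## stage 2: niche shift
  ns <- niche_shift(world$occurrences, world$coastlines, world$grid,
                    source_only = config$source_only,
                    coverage = config$coverage,
                    cell_deg = wc$resolution,
                    seed = child_seed(config$seed, "niche"))
  labels <- ns$classification$populations
  files <- c(files,
             write_csv0(labels, out("niche_labels.csv")),
             write_csv0(ns$scores, out("scores.csv")))
  pca_json <- list(retained_vars = ns$retained_vars,
                   var_frac = as.numeric(ns$pca$var_frac),
                   loadings = apply(ns$pca$loadings, 2, as.numeric,
                                    simplify = FALSE),
                   centroid_shift = as.list(ns$centroid_shift))
  jsonlite::write_json(pca_json, out("pca_model.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, out("pca_model.json"))

  ## stage 3: clone/haploid filter
  cr <- dedupe(geno$genotypes, alpha = config$alpha)
  files <- c(files,
             write_csv0(cr$report, out("clone_report.csv")),
             write_csv0(data.frame(thallus = cr$retained),
                        out("retained_thalli.csv")))

  ## stage 4: phenotype statistics on retained field thalli
  keep <- pheno$stage != "field" | pheno$thallus %in% cr$retained
  assays <- pheno[keep, , drop = FALSE]
  dev_tabs <- lapply(unique(assays$stressor), function(s) {
    deviance_table(assays, s, stage = "field", nodes = config$nodes)
  })
  names(dev_tabs) <- unique(assays$stressor)
  dev_out <- do.call(rbind, lapply(names(dev_tabs), function(s) {
    cbind(stressor = s, as.data.frame(dev_tabs[[s]]))
  }))
  files <- c(files, write_csv0(dev_out, out("deviance_tables.csv")))

  # the O/E split can be degenerate (e.g. every invaded population in
  # expansion space); report the contrast as not estimable in that case
  ove <- tryCatch(
    ove_contrast(assays, labels,
                 exclude = config$exclude_populations,
                 stressor = config$contrast_stressor,
                 nodes = config$nodes),
    error = function(e) list(p = NA_real_, means = NULL, n = NULL,
                             note = conditionMessage(e)))
  jsonlite::write_json(list(p = ove$p, mean_sbs = as.list(ove$means),
                            n = as.list(as.integer(ove$n)),
                            note = ove$note),
                       out("ove_contrast.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, out("ove_contrast.json"))

  sst <- population_sst(world)
  cline <- cline_model(assays, sst, config$cline_coastlines,
                       stressor = config$contrast_stressor,
                       level = config$cline_level,
                       occurrences = world$occurrences,
                       nodes = config$nodes)
  jsonlite::write_json(list(table = as.data.frame(cline$table),
                            slopes = as.list(cline$slopes),
                            sst_lat_r2 = as.list(cline$sst_lat_r2)),
                       out("cline_fit.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, out("cline_fit.json"))

  ## stage 5: darwin rates
  rates <- darwin_rates(assays, years = config$years,
                        epsilon = config$epsilon)
  files <- c(files, write_csv0(rates$cells, out("darwin_rates.csv")))

  report <- list(seed = config$seed,
                 source_only = config$source_only,
                 n_populations = length(unique(world$occurrences$population)),
                 niche_labels = stats::setNames(labels$label,
                                                labels$population),
                 centroid_shift = as.list(ns$centroid_shift),
                 retained_thalli = length(cr$retained),
                 deviance = lapply(dev_tabs, as.data.frame),
                 ove = list(p = ove$p, mean_sbs = as.list(ove$means)),
                 cline_slopes = as.list(cline$slopes),
                 darwins = as.list(rates$summary),
                 files = basename(files))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}
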