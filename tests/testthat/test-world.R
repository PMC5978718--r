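test_that("world generation is deterministic and respects its config", {
  cfg <- world_config(seed = 3)
  w1 <- make_world(cfg)
  w2 <- make_world(cfg)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))

  # every configured climate layer exists on one shared grid
  expect_setequal(names(w1$grid$vars), cfg$climate$var)
  expect_equal(length(w1$grid$vars), 13)

  occ <- w1$occurrences
  # source populations confined to the configured latitude band, native coast
  src <- occ[occ$range_class == "native_source", ]
  expect_equal(nrow(src), cfg$n_source_pops)
  expect_true(all(src$lat >= cfg$source_lat_band[1] &
                    src$lat <= cfg$source_lat_band[2]))
  expect_true(all(src$coastline == "native"))

  # occurrences are snapped to coastal cell centers
  bg <- build_coastal_background(w1$coastlines, cfg$resolution)
  expect_true(all(paste(occ$lon, occ$lat) %in% paste(bg$lon, bg$lat)))
})

test_that("SSTmax declines with latitude and the noiseless limit is exact", {
  w <- make_world(world_config(seed = 3))
  sst <- grid_lookup(w$grid, w$occurrences$lon, w$occurrences$lat, "SSTmax")
  expect_lt(cor(sst[, 1], abs(w$occurrences$lat)), 0)

  # zero noise: every cell equals the analytic gradient formula
  clim <- default_climate_table()
  clim$noise_sd <- 0
  cfg0 <- world_config(seed = 3, climate = clim)
  w0 <- make_world(cfg0)
  for (v in c("SSTmax", "SATrange", "PREC-01")) {
    m <- w0$grid$vars[[v]]
    cx <- w0$grid$xll + (seq_len(w0$grid$ncol) - 0.5) * w0$grid$cellsize
    cy <- w0$grid$yll + (w0$grid$nrow - seq_len(w0$grid$nrow) + 0.5) *
      w0$grid$cellsize
    lon <- matrix(cx, w0$grid$nrow, w0$grid$ncol, byrow = TRUE)
    lat <- matrix(cy, w0$grid$nrow, w0$grid$ncol)
    expect_equal(as.vector(m),
                 climate_mean(cfg0, v, as.vector(lon), as.vector(lat)),
                 tolerance = 1e-12)
  }
})

test_that("invalid world configs are rejected", {
  expect_error(world_config(n_native_pops = 3, n_source_pops = 5))
  expect_error(world_config(resolution = 0))
  clim <- default_climate_table(); clim$noise_sd[1] <- -1
  expect_error(world_config(climate = clim))
  # requesting more source populations than the band holds -> empty world
  expect_error(make_world(world_config(n_native_pops = 40,
                                       n_source_pops = 40)),
               "empty world")
})

test_that("genotype generator plants clones, haploids and a truth table", {
  w <- small_world()
  g <- make_genotypes(w, geno_sim_params(clone_fraction = 0.25,
                                         haploid_fraction = 0.10),
                      seed = 9)
  g2 <- make_genotypes(w, geno_sim_params(clone_fraction = 0.25,
                                          haploid_fraction = 0.10),
                       seed = 9)
  expect_identical(g, g2)

  # 16 thalli per population: 4 clone copies, 2 haploids planted
  per_pop <- split(g$truth, g$truth$population)
  for (tp in per_pop) {
    expect_equal(sum(tp$role == "clone_copy"), 4)
    expect_equal(sum(tp$role == "haploid"), 2)
  }

  # planted clones are exact MLG copies of their progenitor
  loci_cols <- grep("_a[12]$", names(g$genotypes), value = TRUE)
  for (i in which(g$truth$role == "clone_copy")[1:5]) {
    genet <- g$truth$genet[i]
    prog <- g$truth$thallus[g$truth$genet == genet &
                              g$truth$role == "unique_diploid"]
    copy_row <- g$genotypes[g$genotypes$thallus == g$truth$thallus[i],
                            loci_cols]
    prog_row <- g$genotypes[g$genotypes$thallus == prog, loci_cols]
    expect_equal(unname(unlist(copy_row)), unname(unlist(prog_row)))
  }

  # haploids carry one allele per locus
  haps <- g$genotypes$thallus %in%
    g$truth$thallus[g$truth$ploidy == "haploid"]
  a2 <- as.matrix(g$genotypes[haps, grep("_a2$", names(g$genotypes))])
  expect_true(all(is.na(a2)))

  # no clones, no haploids -> all distinct diploid MLGs
  g0 <- make_genotypes(w, geno_sim_params(clone_fraction = 0,
                                          haploid_fraction = 0), seed = 9)
  expect_true(all(g0$truth$role == "unique_diploid"))
  expect_equal(anyDuplicated(g0$truth$genet), 0)

  expect_error(geno_sim_params(clone_fraction = 0.7, haploid_fraction = 0.5))
})

test_that("phenotype generator matches its latent model in the exact limit", {
  w <- small_world()
  # no effects, no random intercepts, zero severity: closed-form multinomial
  theta <- c(0.8, 1.9)
  pp <- pheno_sim_params(cutpoints = theta, beta_region = 0, beta_sst = 0,
                         sigma_pop = 0,
                         severities = list(heat40 = c(x = 0)),
                         thalli_per_pop = 250)
  ph <- make_phenotypes(w, pp, seed = 2, stressors = "heat40")
  expect_true(all(ph$bs_treatment %in% 1:3))
  expect_equal(ph$sbs, ph$bs_treatment - ph$bs_control)

  p_true <- c(plogis(theta[1]), plogis(theta[2]) - plogis(theta[1]),
              1 - plogis(theta[2]))
  n <- nrow(ph)  # 20 pops x 250 thalli = 5000
  expect_gte(n, 5000)
  emp <- tabulate(ph$bs_treatment, 3) / n
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(emp - p_true) <= 3 * se))

  # zero thalli -> empty table
  p0 <- make_phenotypes(w, pheno_sim_params(thalli_per_pop = 0), seed = 1)
  expect_equal(nrow(p0), 0)

  expect_error(pheno_sim_params(cutpoints = c(2, 1)), "increasing")
})

test_that("a planted invaded tolerance advantage lowers invaded bleaching", {
  w <- small_world()
  pp <- pheno_sim_params(beta_region = -1.5, beta_sst = 0, sigma_pop = 0.3,
                         severities = list(heat40 = c("4hr" = 3.5)),
                         thalli_per_pop = 16)
  wins <- 0L
  for (rep in 1:20) {
    ph <- make_phenotypes(w, pp, seed = 100 + rep, stressors = "heat40")
    inv <- proportion_bleached(ph$sbs[ph$range_class == "invaded"])
    nat <- proportion_bleached(ph$sbs[ph$range_class != "invaded"])
    wins <- wins + (inv < nat)
  }
  expect_gte(wins, 19)
})
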