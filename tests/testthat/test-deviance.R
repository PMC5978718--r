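test_that("a planted region-by-level interaction is detected where planted", {
  w <- small_world()
  # effect only at the highest severity level for invaded populations
  base <- pheno_sim_params(beta_region = 0, beta_sst = 0, sigma_pop = 0.3,
                           severities = list(heat40 = c("1hr" = 1.0,
                                                        "2hr" = 1.8,
                                                        "4hr" = 2.6)),
                           thalli_per_pop = 16)
  hits <- 0L
  for (rep in 1:3) {
    ph <- make_phenotypes(w, base, seed = 400 + rep, stressors = "heat40")
    top <- ph$level == "4hr" & ph$range_class == "invaded"
    # re-draw the top-level invaded responses with a -1.5 latent advantage
    set.seed(500 + rep)
    ph$bs_treatment[top] <- sim_ordinal(rep(2.6 - 1.5, sum(top)),
                                        base$cutpoints)
    ph$sbs <- ph$bs_treatment - ph$bs_control
    dt <- deviance_table(ph, "heat40", nonnative = "eNA")
    p_int <- dt$p[dt$term == "interaction"]
    p_top <- dt$p[dt$term == "posthoc:4hr"]
    p_low <- dt$p[dt$term == "posthoc:1hr"]
    hits <- hits + (p_int < 0.05 && p_top < 0.05 && p_low > 0.05)
  }
  expect_gte(hits, 2)
})

test_that("a single population in a region disables the random intercept row", {
  w <- small_world()
  ph <- make_phenotypes(w, pheno_sim_params(thalli_per_pop = 10), seed = 44,
                        stressors = "heat40")
  keep_pops <- c(unique(ph$population[ph$range_class == "native_source"])[1],
                 unique(ph$population[ph$range_class == "invaded"]))
  ph1 <- ph[ph$population %in% keep_pops, ]
  dt <- deviance_table(ph1, "heat40")
  expect_true(is.na(dt$p[dt$term == "(1 | population)"]))
  expect_false(any(is.na(dt$p[dt$term %in% c("region", "treatment",
                                             "interaction")])))
})

test_that("sample sizes report thalli and populations per region", {
  w <- small_world()
  ph <- make_phenotypes(w, pheno_sim_params(thalli_per_pop = 8), seed = 45,
                        stressors = "heat40")
  dt <- deviance_table(ph, "heat40")
  sizes <- attr(dt, "sizes")
  expect_equal(sizes$thalli[sizes$region == "native"], 2 * 8)
  expect_equal(sizes$populations[sizes$region == "nonnative"], 15)
})

test_that("the O-vs-E contrast detects a planted expansion advantage", {
  w <- small_world()
  labels <- data.frame(
    population = unique(w$occurrences$population),
    stringsAsFactors = FALSE)
  cls <- w$occurrences$range_class[match(labels$population,
                                         w$occurrences$population)]
  # construct labels: native-overlapping invaded pops O, the rest E
  labels$label <- ifelse(cls != "invaded", "outside",
                         rep(c("O", "E"), length.out = nrow(labels)))
  e_pops <- labels$population[labels$label == "E"]
  eff <- stats::setNames(rep(-1.5, length(e_pops)), e_pops)
  pp <- pheno_sim_params(beta_region = 0, beta_sst = 0, sigma_pop = 0.3,
                         severities = list(heat40 = c("4hr" = 3.0)),
                         thalli_per_pop = 16)
  ph <- make_phenotypes(w, pp, seed = 46, stressors = "heat40",
                        pop_effects = eff)
  ov <- ove_contrast(ph, labels, stressor = "heat40")
  expect_lt(ov$p, 0.05)
  expect_lt(ov$means[["E"]], ov$means[["O"]])
  # exclusions really drop populations from the fitted data
  excl <- labels$population[labels$label == "O"][1]
  ov2 <- ove_contrast(ph, labels, exclude = excl, stressor = "heat40")
  expect_equal(sum(ov2$n), sum(ph$population %in%
                                 setdiff(labels$population[labels$label %in%
                                                             c("O", "E")],
                                         excl)))
  # both groups must be present
  only_o <- labels; only_o$label[only_o$label == "E"] <- "outside"
  expect_error(ove_contrast(ph, only_o, stressor = "heat40"), "empty")
})

test_that("cline models recover planted parallel clines and symmetry", {
  w <- small_world()
  # planted SST cline, no extra region effect at the latent level
  pp <- pheno_sim_params(beta_region = -1.0, beta_sst = -0.25,
                         sigma_pop = 0.25,
                         severities = list(heat40 = c("4hr" = 3.0)),
                         thalli_per_pop = 16)
  ph <- make_phenotypes(w, pp, seed = 47, stressors = "heat40")
  sst <- nicheshift:::population_sst(w)
  cl <- cline_model(ph, sst, c("native", "eNA"), level = "4hr",
                    occurrences = w$occurrences)
  # slope sign recovered in both regions; parallel planted clines leave the
  # interaction non-significant
  expect_lt(cl$slopes[["native"]], 0)
  expect_lt(cl$slopes[["nonnative"]], 0)
  expect_gt(cl$table$p[cl$table$term == "interaction"], 0.05)
  # prediction curves cover both regions over the observed SST range
  expect_setequal(unique(cl$curves$region), c("native", "eNA"))
  expect_true(all(cl$curves$p_bleached >= 0 & cl$curves$p_bleached <= 1))
  # SST tracks |latitude| strongly along each synthetic coastline
  expect_true(all(cl$sst_lat_r2 > 0.5))

  # identical populations duplicated into both regions: region coef ~ 0
  dup <- ph[ph$coastline == "eNA" & ph$level == "4hr", ]
  dup2 <- dup
  dup2$coastline <- "fake"
  dup2$thallus <- paste0(dup2$thallus, "x")
  both <- rbind(dup, dup2)
  cl2 <- cline_model(both, sst, c("eNA", "fake"), level = "4hr")
  reg_ix <- grep("^region", names(cl2$fit$beta))
  expect_lt(abs(cl2$fit$beta[reg_ix]), 0.05)
  # constant SST in both regions is not estimable
  sst_const <- sst; sst_const[] <- 15
  expect_error(cline_model(ph, sst_const, c("native", "eNA"), level = "4hr"),
               "constant|estimable")
})
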