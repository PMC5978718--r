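test_that("the full niche-shift analysis behaves on a synthetic world", {
  w <- make_world(world_config(seed = 7))
  ns <- niche_shift(w$occurrences, w$coastlines, w$grid, source_only = TRUE,
                    seed = 3)
  # retained variables all below the correlation threshold
  env <- rbind(extract_env_all(ns$background, w$grid,
                               seed = nicheshift:::child_seed(3, "bg")))
  r <- abs(cor(env[, ns$retained_vars]))
  diag(r) <- 0
  expect_lt(max(r), 0.95)  # background-only correlations near threshold

  # background scores center at zero is not expected (joint fit), but the
  # combined fitting set is centered
  all_sc <- rbind(ns$pca$scores_background, ns$pca$scores_occurrences)
  expect_true(all(abs(colMeans(all_sc)) < 1e-9))

  # population labels form a partition and invaded pops are mostly E/O
  labs <- ns$classification$populations
  expect_true(all(labs$label %in% c("O", "E", "U", "outside")))
  inv_pops <- unique(w$occurrences$population[
    w$occurrences$range_class == "invaded"])
  inv_labs <- labs$label[labs$population %in% inv_pops]
  expect_gt(mean(inv_labs %in% c("O", "E")), 0.8)

  # planted warming of invaded coastlines: centroid shifts toward warmer
  # (lower PC1 when SSTmean loads negatively, i.e. along the temperature
  # axis); assert a nonzero shift with reproducible sign
  expect_gt(sum(abs(ns$centroid_shift)), 0.1)
  ns2 <- niche_shift(w$occurrences, w$coastlines, w$grid,
                     source_only = TRUE, seed = 3)
  expect_equal(ns$centroid_shift, ns2$centroid_shift)
})

test_that("restricting the native side to the source subset shrinks its region", {
  w <- make_world(world_config(seed = 7))
  ns_src <- niche_shift(w$occurrences, w$coastlines, w$grid,
                        source_only = TRUE, seed = 3)
  ns_all <- niche_shift(w$occurrences, w$coastlines, w$grid,
                        source_only = FALSE, seed = 3)
  # the source occurrences are a subset of the native occurrences, and the
  # source pool sits in a colder band: the genetically informed native
  # region must not classify more invaded populations as overlapping
  labs_src <- ns_src$classification$populations
  labs_all <- ns_all$classification$populations
  inv <- unique(w$occurrences$population[
    w$occurrences$range_class == "invaded"])
  o_src <- sum(labs_src$label[labs_src$population %in% inv] == "O")
  o_all <- sum(labs_all$label[labs_all$population %in% inv] == "O")
  e_src <- sum(labs_src$label[labs_src$population %in% inv] == "E")
  e_all <- sum(labs_all$label[labs_all$population %in% inv] == "E")
  expect_lte(o_src, o_all)
  expect_gte(e_src, e_all)
})

test_that("nested score clouds give nested kernel regions on a shared grid", {
  set.seed(60)
  full <- cbind(rnorm(400, 0, 1.5), rnorm(400, 0, 1.5))
  subset_pts <- full[full[, 1] < 0, ]  # colder half as "source"
  eval_grid <- list(x = seq(-8, 8, length.out = 150),
                    y = seq(-8, 8, length.out = 150))
  r_full <- kde_region(full, 0.99, eval_grid = eval_grid)
  r_sub <- kde_region(subset_pts, 0.99, eval_grid = eval_grid)
  # the subset region adds little area outside the full region
  extra <- sum(r_sub$mask & !r_full$mask) / sum(r_sub$mask)
  expect_lt(extra, 0.12)
  expect_lt(region_area(r_sub), region_area(r_full))
})
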