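geno_row <- function(pop, thallus, ...) {
  alleles <- list(...)
  row <- c(list(population = pop, thallus = thallus), alleles)
  as.data.frame(row, stringsAsFactors = FALSE)
}

test_that("one heterozygous locus makes a thallus diploid", {
  g <- rbind(
    geno_row("p", "het", L1_a1 = 120L, L1_a2 = 124L, L2_a1 = 100L,
             L2_a2 = 100L),
    geno_row("p", "hom", L1_a1 = 120L, L1_a2 = 120L, L2_a1 = 100L,
             L2_a2 = 100L),
    geno_row("p", "hap", L1_a1 = 120L, L1_a2 = NA, L2_a1 = 100L, L2_a2 = NA))
  expect_equal(infer_ploidy(g), c("diploid", "haploid", "haploid"))
  g_missing <- geno_row("p", "x", L1_a1 = NA, L1_a2 = NA, L2_a1 = NA,
                        L2_a2 = NA)
  expect_error(infer_ploidy(g_missing), "unscorable")
})

test_that("pgen follows Hardy-Weinberg genotype probabilities", {
  freqs <- list(L1 = c("1" = 0.5, "2" = 0.5), L2 = c("1" = 0.5, "2" = 0.5))
  het1 <- geno_row("p", "a", L1_a1 = 1L, L1_a2 = 2L, L2_a1 = NA, L2_a2 = NA)
  expect_equal(pgen(het1, freqs), 0.5)            # 2 x 0.5 x 0.5
  het2 <- geno_row("p", "b", L1_a1 = 1L, L1_a2 = 2L, L2_a1 = 1L, L2_a2 = 2L)
  expect_equal(pgen(het2, freqs), 0.25)           # product over loci
  # locus order permutation
  freqs_swapped <- freqs[c("L2", "L1")]
  expect_equal(pgen(het2, freqs_swapped), 0.25)
  # unknown allele is an error
  bad <- geno_row("p", "c", L1_a1 = 9L, L1_a2 = 9L, L2_a1 = 1L, L2_a2 = 1L)
  expect_error(pgen(bad, freqs), "absent")
})

test_that("pgen sums to 1 over all diploid genotypes (brute force)", {
  freqs <- list(L1 = c("1" = 0.6, "2" = 0.4), L2 = c("3" = 0.3, "4" = 0.7))
  combos <- expand.grid(a1 = 1:2, a2 = 1:2, b1 = 3:4, b2 = 3:4)
  combos <- combos[combos$a1 <= combos$a2 & combos$b1 <= combos$b2, ]
  expect_equal(nrow(combos), 9)  # 3 genotypes per locus, 2 loci
  tot <- sum(vapply(seq_len(nrow(combos)), function(i) {
    g <- geno_row("p", "x", L1_a1 = combos$a1[i], L1_a2 = combos$a2[i],
                  L2_a1 = combos$b1[i], L2_a2 = combos$b2[i])
    pgen(g, freqs)
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("psex is the binomial recurrence tail", {
  expect_equal(psex(0, 1, 10), 0)
  expect_equal(psex(1, 1, 10), 1)
  expect_equal(psex(0.5, 2, 3), 0.5)  # (C(3,2) + C(3,3)) / 8
  # monotone in pgen
  p <- sapply(seq(0.05, 0.95, by = 0.1), psex, n_observed = 3, N_sampled = 10)
  expect_true(all(diff(p) > 0))
  expect_error(psex(0.5, 5, 3), "exceeds")
})

test_that("dedupe keeps unique diploids and drops clones and haploids", {
  # all-distinct diploids: nothing dropped
  set.seed(20)
  w <- small_world()
  g0 <- make_genotypes(w, geno_sim_params(clone_fraction = 0,
                                          haploid_fraction = 0), seed = 3)
  cr0 <- dedupe(g0$genotypes)
  expect_equal(length(cr0$retained), nrow(g0$genotypes))

  # four copies of a rare genotype: three dropped, one kept
  base <- lapply(1:8, function(i) {
    stats::setNames(as.list(as.integer(c(100 + 2 * ((i * 7) %% 5),
                                         100 + 2 * ((i * 3) %% 5)))),
                    c("L1_a1", "L1_a2"))
  })
  rows <- do.call(rbind, lapply(seq_along(base), function(i)
    as.data.frame(c(list(population = "p",
                         thallus = sprintf("t%02d", i),
                         L2_a1 = 100L + 2L * (i %% 6),
                         L2_a2 = 100L + 2L * ((i + 2) %% 6),
                         L3_a1 = 100L + 2L * ((3 * i) %% 6),
                         L3_a2 = 100L + 2L * ((i + 4) %% 6),
                         L4_a1 = 102L, L4_a2 = 104L,
                         L5_a1 = 106L, L5_a2 = 108L),
                    base[[i]]))))
  clone <- rows[1, ]
  copies <- do.call(rbind, lapply(1:3, function(j) {
    r <- clone; r$thallus <- paste0("c", j); r
  }))
  tab <- rbind(rows, copies)
  cr <- dedupe(tab, alpha = 0.05, min_shared = 5)
  rep_clone <- cr$report[cr$report$thallus %in%
                           c(clone$thallus, paste0("c", 1:3)), ]
  expect_equal(sum(rep_clone$keep), 1)
  expect_equal(rep_clone$thallus[rep_clone$keep], clone$thallus)
  expect_true(all(rep_clone$psex < 0.05))

  # idempotence: rerunning on the retained set drops nothing further
  kept <- tab[tab$thallus %in% cr$retained, ]
  cr2 <- dedupe(kept, alpha = 0.05, min_shared = 5)
  expect_setequal(cr2$retained, cr$retained)

  # no haploids and no duplicate MLGs in any output
  w2 <- small_world(seed = 8)
  g <- make_genotypes(w2, geno_sim_params(), seed = 8)
  crr <- dedupe(g$genotypes)
  kept_rows <- crr$report[crr$report$keep, ]
  expect_true(all(kept_rows$ploidy == "diploid"))
  expect_equal(anyDuplicated(kept_rows$mlg), 0)

  expect_warning(dedupe(g$genotypes[0, ]), "empty")
})

test_that("planted clonal structure is recovered exactly from the truth table", {
  w <- small_world(seed = 12)
  g <- make_genotypes(w, geno_sim_params(clone_fraction = 0.25,
                                         haploid_fraction = 0.10), seed = 12)
  cr <- dedupe(g$genotypes)
  truth_genets <- unique(g$truth$genet[g$truth$ploidy == "diploid"])
  kept_genets <- g$truth$genet[g$truth$thallus %in% cr$retained]
  expect_equal(anyDuplicated(kept_genets), 0)
  expect_setequal(kept_genets, truth_genets)
})

test_that("psex matches Monte-Carlo recurrence frequency under HWE", {
  freqs <- list(L1 = c("1" = 0.7, "2" = 0.3), L2 = c("3" = 0.6, "4" = 0.4))
  # target genotype: heterozygous at both loci
  pg <- 2 * 0.7 * 0.3 * 2 * 0.6 * 0.4  # 0.2016
  N <- 10; n_obs <- 2; reps <- 1e5
  set.seed(99)
  # draw reps x N multilocus genotypes and count the target
  draw_match <- function() {
    a <- matrix(sample(1:2, reps * N * 2, TRUE, prob = c(0.7, 0.3)),
                ncol = 2)
    b <- matrix(sample(3:4, reps * N * 2, TRUE, prob = c(0.6, 0.4)),
                ncol = 2)
    hit <- (pmin(a[, 1], a[, 2]) == 1 & pmax(a[, 1], a[, 2]) == 2) &
      (pmin(b[, 1], b[, 2]) == 3 & pmax(b[, 1], b[, 2]) == 4)
    matrix(hit, nrow = reps)
  }
  counts <- rowSums(draw_match())
  mc <- mean(counts >= n_obs)
  se <- sqrt(mc * (1 - mc) / reps)
  expect_equal(psex(pg, n_obs, N), mc, tolerance = 3 * se / mc)
})
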