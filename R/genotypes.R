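## Synthetic multilocus microsatellite genotypes: unique diploid genets,
## planted clonal copies, and haploids, with a truth table for recovery tests.

#' Parameters for the genotype generator
#'
#' @param n_loci Number of microsatellite loci (default 10).
#' @param n_alleles Alleles segregating per locus (>= 2).
#' @param freq_conc Dirichlet concentration for per-population allele
#'   frequencies (1 = uniform over the simplex).
#' @param clone_fraction Fraction of thalli per population that are clonal
#'   copies of a progenitor genet.
#' @param haploid_fraction Fraction of thalli per population that are
#'   haploids (one allele per locus).
#' @param thalli_per_pop Thalli genotyped per population (default 16).
#' @return Object of class `geno_sim_params`.
#' @export
geno_sim_params <- function(n_loci = 10L, n_alleles = 6L, freq_conc = 1,
                            clone_fraction = 0.25, haploid_fraction = 0.10,
                            thalli_per_pop = 16L) {
  stopifnot(n_loci >= 1, n_alleles >= 2,
            clone_fraction >= 0, clone_fraction <= 1,
            haploid_fraction >= 0, haploid_fraction <= 1,
            thalli_per_pop >= 0)
  if (clone_fraction + haploid_fraction > 1) {
    stop("clone_fraction + haploid_fraction must not exceed 1")
  }
  structure(list(n_loci = as.integer(n_loci),
                 n_alleles = as.integer(n_alleles),
                 freq_conc = freq_conc,
                 clone_fraction = clone_fraction,
                 haploid_fraction = haploid_fraction,
                 thalli_per_pop = as.integer(thalli_per_pop)),
            class = "geno_sim_params")
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

mlg_key <- function(mat) {
  # mat: n_loci x 2 allele matrix (haploid: col 2 NA); canonical string key
  apply(mat, 1, function(a) {
    a <- sort(a[!is.na(a)])
    paste(a, collapse = "/")
  }) |> paste(collapse = "|")
}

#' Generate synthetic genotypes with planted clones and haploids
#'
#' For every population in the world, draws per-population allele
#' frequencies, then fills `thalli_per_pop` thalli with (i) unique diploid
#' genets drawn under Hardy-Weinberg proportions, (ii) exact clonal copies of
#' randomly chosen progenitor genets, and (iii) haploids carrying one allele
#' per locus. Unique diploids are redrawn on the (rare) event of an exact
#' multilocus collision or an all-homozygous draw, so planted genet identity
#' is unambiguous. A truth table records every planted genet and ploidy.
#'
#' @param world A [make_world()] result (only population labels are used).
#' @param params A [geno_sim_params()].
#' @param seed Integer seed.
#' @return List with `genotypes` (wide data frame: `population`, `thallus`,
#'   then `L<k>_a1`, `L<k>_a2` per locus; `NA` = missing/absent second
#'   allele) and `truth` (`thallus`, `population`, `genet`, `ploidy`,
#'   `role`).
#' @export
make_genotypes <- function(world, params = geno_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "geno_sim_params"))
  pops <- unique(world$occurrences$population)
  if (length(pops) == 0) stop("no populations in world")
  loci <- sprintf("L%02d", seq_len(params$n_loci))
  allele_sizes <- 100L + 2L * seq_len(params$n_alleles)

  n <- params$thalli_per_pop
  n_clone <- round(params$clone_fraction * n)
  n_hap <- round(params$haploid_fraction * n)
  n_uni <- n - n_clone - n_hap
  if (n > 0 && n_clone > 0 && n_uni < 1) {
    stop("need at least one unique diploid progenitor for planted clones")
  }

  with_seed(child_seed(seed, "genotypes"), {
    geno_rows <- list(); truth_rows <- list(); k <- 0L
    for (pop in pops) {
      if (n == 0) next
      freqs <- lapply(seq_len(params$n_loci),
                      function(i) rdirichlet1(params$n_alleles,
                                              params$freq_conc))
      draw_dip <- function() {
        m <- vapply(freqs, function(p) sample(allele_sizes, 2, replace = TRUE,
                                              prob = p), integer(2))
        t(m) # n_loci x 2
      }
      draw_hap <- function() {
        a <- vapply(freqs, function(p) sample(allele_sizes, 1, prob = p),
                    integer(1))
        cbind(a, NA_integer_)
      }
      uniques <- list(); seen <- character(0)
      for (i in seq_len(n_uni)) {
        repeat {
          g <- draw_dip()
          key <- mlg_key(g)
          het <- any(g[, 1] != g[, 2])
          if (het && !(key %in% seen)) break
        }
        seen <- c(seen, key)
        uniques[[i]] <- g
      }
      progenitors <- if (n_clone > 0) sample(n_uni, n_clone, replace = TRUE)
      else integer(0)

      mats <- c(uniques,
                lapply(progenitors, function(i) uniques[[i]]),
                replicate(n_hap, draw_hap(), simplify = FALSE))
      genet <- c(sprintf("%s-g%02d", pop, seq_len(n_uni)),
                 sprintf("%s-g%02d", pop, progenitors),
                 sprintf("%s-h%02d", pop, seq_len(n_hap)))
      role <- rep(c("unique_diploid", "clone_copy", "haploid"),
                  c(n_uni, n_clone, n_hap))
      ploidy <- rep(c("diploid", "diploid", "haploid"),
                    c(n_uni, n_clone, n_hap))
      ord <- sample(n)
      for (t in seq_len(n)) {
        k <- k + 1L
        m <- mats[[ord[t]]]
        row <- as.list(as.vector(t(m)))
        names(row) <- as.vector(t(outer(loci, c("_a1", "_a2"), paste0)))
        geno_rows[[k]] <- c(list(population = pop,
                                 thallus = sprintf("%s-t%02d", pop, t)), row)
        truth_rows[[k]] <- data.frame(
          thallus = sprintf("%s-t%02d", pop, t), population = pop,
          genet = genet[ord[t]], ploidy = ploidy[ord[t]],
          role = role[ord[t]], stringsAsFactors = FALSE)
      }
    }
    if (k == 0L) {
      return(list(genotypes = data.frame(population = character(0),
                                         thallus = character(0)),
                  truth = data.frame(thallus = character(0),
                                     population = character(0),
                                     genet = character(0),
                                     ploidy = character(0),
                                     role = character(0))))
    }
    genotypes <- do.call(rbind, lapply(geno_rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    truth <- do.call(rbind, truth_rows)
    rownames(genotypes) <- rownames(truth) <- NULL
    list(genotypes = genotypes, truth = truth)
  })
}
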