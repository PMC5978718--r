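## Clone and ploidy filtering of multilocus microsatellite genotypes:
## heterozygosity-based ploidy calls, Hardy-Weinberg genotype probabilities
## (pgen), the Psex test for repeated multilocus genotypes, and the
## unique-diploid-genet dataset used by the phenotype analyses.

# Column names "<locus>_a1"/"<locus>_a2" -> locus names, in table order.
genotype_loci <- function(genotypes) {
  a1 <- grep("_a1$", names(genotypes), value = TRUE)
  loci <- sub("_a1$", "", a1)
  if (length(loci) == 0) stop("no locus columns (<locus>_a1/_a2) found")
  loci
}

# n x n_loci matrices of first/second alleles for a genotype table.
allele_matrices <- function(genotypes, loci = genotype_loci(genotypes)) {
  a1 <- as.matrix(genotypes[, paste0(loci, "_a1"), drop = FALSE])
  a2 <- as.matrix(genotypes[, paste0(loci, "_a2"), drop = FALSE])
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  list(a1 = a1, a2 = a2, loci = loci)
}

#' Ploidy call from a multilocus genotype
#'
#' A thallus is called diploid when at least one scored locus carries two
#' distinct alleles (one heterozygous locus suffices); otherwise it is
#' called haploid. Thalli that are homozygous at every locus are therefore
#' indistinguishable from haploids and are called haploid by this rule.
#'
#' @param genotypes Genotype data frame (wide, `<locus>_a1`/`<locus>_a2`
#'   columns; `NA` = missing).
#' @return Character vector `"haploid"`/`"diploid"`, one per row.
#' @export
infer_ploidy <- function(genotypes) {
  am <- allele_matrices(genotypes)
  scored <- !is.na(am$a1) | !is.na(am$a2)
  if (any(rowSums(scored) == 0)) {
    bad <- which(rowSums(scored) == 0)
    stop("unscorable: all loci missing for row(s) ",
         paste(bad, collapse = ", "))
  }
  het <- !is.na(am$a1) & !is.na(am$a2) & am$a1 != am$a2
  ifelse(rowSums(het) > 0, "diploid", "haploid")
}

#' Per-population allele frequencies
#'
#' Relative allele frequencies per locus from all non-missing allele calls
#' of one population's genotypes.
#'
#' @param genotypes Genotype rows of a single population.
#' @return Named list per locus of named frequency vectors (allele ->
#'   frequency, summing to 1).
#' @export
allele_freqs <- function(genotypes) {
  am <- allele_matrices(genotypes)
  out <- lapply(seq_along(am$loci), function(j) {
    alleles <- c(am$a1[, j], am$a2[, j])
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) return(stats::setNames(numeric(0), character(0)))
    tab <- table(alleles)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(out) <- am$loci
  out
}

#' Hardy-Weinberg probability of a diploid multilocus genotype (pgen)
#'
#' Product over scored loci of `p^2` for homozygotes and `2 p q` for
#' heterozygotes, from population allele frequencies. Missing loci are
#' skipped. Invariant to locus order.
#'
#' @param genotype One genotype row (data frame or list with
#'   `<locus>_a1`/`<locus>_a2` entries).
#' @param freqs [allele_freqs()] list covering the genotype's alleles.
#' @return Probability in (0, 1].
#' @export
pgen <- function(genotype, freqs) {
  g <- as.data.frame(genotype)
  am <- allele_matrices(g, loci = names(freqs))
  p <- 1
  for (j in seq_along(freqs)) {
    a1 <- am$a1[1, j]; a2 <- am$a2[1, j]
    if (is.na(a1) || is.na(a2)) next  # incompletely scored locus: skipped
    f <- freqs[[j]]
    f1 <- f[as.character(a1)]; f2 <- f[as.character(a2)]
    if (is.na(f1) || is.na(f2)) {
      stop("allele absent from frequency table at locus ", names(freqs)[j])
    }
    p <- p * if (a1 == a2) f1^2 else 2 * f1 * f2
  }
  unname(p)
}

#' Probability that a repeated genotype arose sexually (Psex)
#'
#' Binomial upper tail: the probability that a multilocus genotype with
#' Hardy-Weinberg probability `pgen` recurs at least `n_observed` times
#' among `N_sampled` independent sexual events. Small values indicate the
#' repeats are clonal ramets.
#'
#' @param pgen_value Genotype probability in `[0, 1]`.
#' @param n_observed Number of thalli carrying the genotype (>= 1).
#' @param N_sampled Number of thalli sampled in the population.
#' @return Probability in `[0, 1]`, monotone increasing in `pgen_value`.
#' @export
psex <- function(pgen_value, n_observed, N_sampled) {
  stopifnot(pgen_value >= 0, pgen_value <= 1, n_observed >= 1)
  if (n_observed > N_sampled) stop("n_observed exceeds N_sampled")
  stats::pbinom(n_observed - 1, N_sampled, pgen_value, lower.tail = FALSE)
}

# Do two thalli carry the same MLG? Loci missing in either are excluded;
# fewer than `min_shared` mutually scored loci makes them unmatchable.
same_mlg <- function(am, i, j, min_shared = 5L) {
  s1 <- !is.na(am$a1[i, ]); s2 <- !is.na(am$a1[j, ])
  shared <- s1 & s2
  if (sum(shared) < min_shared) return(FALSE)
  lo_i <- pmin(am$a1[i, shared], am$a2[i, shared], na.rm = TRUE)
  hi_i <- pmax(am$a1[i, shared], am$a2[i, shared], na.rm = TRUE)
  lo_j <- pmin(am$a1[j, shared], am$a2[j, shared], na.rm = TRUE)
  hi_j <- pmax(am$a1[j, shared], am$a2[j, shared], na.rm = TRUE)
  all(lo_i == lo_j & hi_i == hi_j)
}

#' Remove haploids and clonal replicates from a genotype table
#'
#' Per population: calls ploidy, groups diploids that share an identical
#' multilocus genotype over their mutually scored loci, computes `pgen` from
#' per-population allele frequencies (after provisionally collapsing exact
#' duplicates once, to reduce clonal inflation) and flags repeated genotypes
#' with `Psex < alpha` as clones. Haploids and all but the first ramet (in
#' input order) of each clonal genet are dropped; repeated genotypes whose
#' Psex exceeds `alpha` are retained as plausible independent sexual events.
#'
#' @param genotypes Wide genotype data frame with `population` and `thallus`
#'   columns plus `<locus>_a1`/`<locus>_a2` pairs.
#' @param alpha Psex significance threshold (default 0.05).
#' @param min_shared Minimum mutually scored loci for two thalli to be
#'   matchable as the same genet (default 5).
#' @param collapse_duplicates_for_freqs Compute allele frequencies after one
#'   round of exact-duplicate removal (default TRUE).
#' @return Object of class `clone_report`: `report` (per thallus: `mlg`,
#'   `ploidy`, `pgen`, `psex`, `keep`, `reason`), `retained` (kept thallus
#'   ids), `summary` (per population: thalli, unique genets, haploids,
#'   clones dropped).
#' @export
dedupe <- function(genotypes, alpha = 0.05, min_shared = 5L,
                   collapse_duplicates_for_freqs = TRUE) {
  if (nrow(genotypes) == 0) {
    warning("empty genotype table")
    return(structure(list(report = data.frame(), retained = character(0),
                          summary = data.frame()), class = "clone_report"))
  }
  reports <- list()
  for (pop in unique(genotypes$population)) {
    g <- genotypes[genotypes$population == pop, , drop = FALSE]
    am <- allele_matrices(g)
    n <- nrow(g)
    ploidy <- infer_ploidy(g)

    # group identical MLGs among diploids (union-find over pairwise matches)
    grp <- seq_len(n)
    find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
    dips <- which(ploidy == "diploid")
    if (length(dips) > 1) {
      for (ii in seq_along(dips)[-1]) {
        for (jj in seq_len(ii - 1)) {
          i <- dips[ii]; j <- dips[jj]
          if (same_mlg(am, i, j, min_shared)) {
            grp[find(i)] <- find(j)
            break
          }
        }
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    mlg_id <- match(root, unique(root[order(seq_len(n))]))
    mlg <- sprintf("%s-mlg%02d", pop, mlg_id)

    # allele frequencies, optionally on provisionally deduplicated rows
    freq_rows <- if (collapse_duplicates_for_freqs) {
      !duplicated(root)
    } else rep(TRUE, n)
    freqs <- allele_freqs(g[freq_rows, , drop = FALSE])

    pg <- rep(NA_real_, n); ps <- rep(NA_real_, n)
    keep <- rep(TRUE, n); reason <- rep("unique_diploid", n)
    keep[ploidy == "haploid"] <- FALSE
    reason[ploidy == "haploid"] <- "haploid"
    for (r in unique(root[ploidy == "diploid"])) {
      members <- which(root == r & ploidy == "diploid")
      pgv <- pgen(g[members[1], , drop = FALSE], freqs)
      pg[members] <- pgv
      if (length(members) > 1) {
        psv <- psex(pgv, length(members), n)
        ps[members] <- psv
        if (psv < alpha) {
          drop <- members[-1]  # keep first ramet by input order
          keep[drop] <- FALSE
          reason[drop] <- "clone"
          reason[members[1]] <- "clonal_genet_kept"
        } else {
          reason[members] <- "repeated_mlg_retained"
        }
      }
    }
    reports[[pop]] <- data.frame(
      thallus = g$thallus, population = pop, mlg = mlg, ploidy = ploidy,
      pgen = pg, psex = ps, keep = keep, reason = reason,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, c(reports, make.row.names = FALSE))
  summary <- do.call(rbind, lapply(split(report, report$population),
    function(r) data.frame(
      population = r$population[1], thalli = nrow(r),
      unique_genets = length(unique(r$mlg[r$ploidy == "diploid"])),
      haploids = sum(r$ploidy == "haploid"),
      clones_dropped = sum(r$reason == "clone"),
      retained = sum(r$keep), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(report = report, retained = report$thallus[report$keep],
                 summary = summary),
            class = "clone_report")
}

#' @export
print.clone_report <- function(x, ...) {
  cat(sprintf("<clone_report> %d thalli, %d retained (%d haploids, %d clones dropped)\n",
              nrow(x$report), length(x$retained),
              sum(x$report$reason == "haploid"),
              sum(x$report$reason == "clone")))
  invisible(x)
}
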