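# nicheshift

Genetically informed climatic niche-shift analysis and downstream inference
of phenotypic evolution for coastal invasive species.

## The problem

Invasions often start from a geographically restricted subset of a species'
native range. A niche comparison against the *whole* native range can then
hide — or reverse the apparent direction of — a real climatic niche shift.
When the source populations are known from population genetics, the right
comparison is **source versus invaded**: the parts of climate space the
invasion occupies that the source never did (*Expansion*, E) are exactly
where evolved shifts in stress tolerance are predicted, relative to
populations in the shared climate space (*Overlap*, O). Tolerance change
over the invasion timescale can then be expressed as a rate of phenotypic
evolution.

`nicheshift` is aimed at invasion ecologists and evolutionary biologists
with (i) occurrence records classed as native-source / native-nonsource /
invaded, (ii) gridded coastal climate layers, (iii) multilocus
microsatellite genotypes of assayed individuals, and (iv) ordinal
stress-assay scores (the motivating system is bleaching of a haplodiplontic
red seaweed under heat, cold and low-salinity stress).

## What it computes

* **PCAenv** — correlation PCA of climate variables over coastal background
  cells (1° grid cells intersecting a coastline) plus occurrence sites,
  after buffered extraction (mean of 50 samples in a 50-km disk per site)
  and a greedy `|r| < 0.9` collinearity filter.
* **Niche regions and O/E/U** — 99% highest-density regions of a
  full-covariance Gaussian KDE (Scott's rule, `H = n^(-1/3) S`) in PC1×PC2,
  for the native-source and invaded score clouds; cell-level set algebra
  gives Overlap / Expansion / Unfilled space, population labels, and the
  centroid shift of realized niche space.
* **Clone & ploidy filter** — diploids called by ≥1 heterozygous
  microsatellite locus; repeated multilocus genotypes tested with
  `Psex = Σ_{j≥n} C(N,j) p_gen^j (1−p_gen)^{N−j}` (binomial recurrence tail
  with Hardy–Weinberg `p_gen`); haploids and significant clonal ramets
  dropped, one ramet per genet kept.
* **Ordinal phenotype battery** — proportional-odds cumulative-link models
  of the Standardized Bleach Score (`SBS = BS_trt − BS_ctrl`), with a
  population random intercept integrated by adaptive Gauss–Hermite
  quadrature (15 nodes): region × treatment analysis-of-deviance tables
  with likelihood-ratio p-values and per-level post hoc contrasts, the
  O-vs-E phenotype contrast, and ANCOVA-like latitudinal cline models
  against population SSTmax.
* **Darwin rates** — `|ln(x2/x1)| / (years/10^6)` on the proportion-bleached
  trait, averaged over invaded-coastline × treatment cells per stressor.
* **A seeded synthetic world** — coastlines, 13 climate layers, occurrences
  with a cold/seasonal source band, genotypes with planted clones and
  haploids (with truth table), and latent-model ordinal phenotypes — so the
  entire pipeline runs and is tested without any external data.

## Worked example

```r
library(nicheshift)

world <- make_world(world_config(seed = 1))
ns <- niche_shift(world$occurrences, world$coastlines, world$grid,
                  source_only = TRUE, seed = 1)
ns
#> <niche_shift> (source-only native niche)
#> retained variables: SAL, SATmax, SATmin, SSTrange, PREC-01, PREC-04, PREC-07, PREC-10
#> PC1 + PC2 explain 72.6% of variance
#> centroid shift: dPC1 = 1.397, dPC2 = -1.341
#> <niche_classification>
#> cells: E=5995, O=1354, outside=31069, U=1582
#> populations: E=21, O=9, outside=4, U=6
```

The centroid arrow and the 21 invaded populations in Expansion space say
the invasion moved into climate space the source band never occupied
(warmer, less seasonal — positive ΔPC1 along the warm direction, negative
ΔPC2 along seasonality for this seed's loadings).

```r
geno <- make_genotypes(world, seed = 1)
keep <- dedupe(geno$genotypes)
keep
#> <clone_report> 640 thalli, 400 retained (80 haploids, 160 clones dropped)

assays <- make_phenotypes(world, seed = 1)
field <- assays[assays$thallus %in% keep$retained, ]
deviance_table(field, "heat40")
#> Analysis of deviance (heat40, field)
#>              term df statistic        p
#>  (1 | population)  1    18.744 1.49e-05
#>           overall  5   114.819 3.92e-23
#>            region  1    10.021 1.55e-03
#>         treatment  2    33.709 4.79e-08
#>       interaction  2     1.795 4.08e-01
#>       posthoc:1hr  1     9.168 2.46e-03
#>       posthoc:2hr  1    22.630 1.96e-06
#>       posthoc:4hr  1    17.839 2.40e-05
#> sample sizes: native 60 (6), nonnative 250 (25)
```

The region row (p = 0.0016) is the headline test: after the clone/haploid
filter, invaded populations bleach less than native-source populations
under 40 °C heat stress, at every exposure length (post hoc rows). The
niche-based contrast and the evolutionary rates follow the same pattern:

```r
ove <- ove_contrast(field, ns$classification$populations)
sprintf("O-vs-E: p = %.3g; mean SBS O = %.2f, E = %.2f",
        ove$p, ove$means[["O"]], ove$means[["E"]])
#> "O-vs-E: p = 0.00911; mean SBS O = 0.50, E = 0.29"

round(darwin_rates(field)$summary)
#>  coldm20   heat40 salinity
#>    11811    11006    13998
```

Populations in Expansion niche space are more heat tolerant than Overlap
populations (lower mean SBS), and the implied rates of tolerance evolution
over a 100-year invasion are on the order of 10^4 darwins.

`run_pipeline(run_config(seed = 1, outdir = "run1"))` executes all stages
(simulate → niche shift → clone filter → phenotype statistics → rates) and
writes CSV/JSON outputs plus a manifest under one directory; reruns with
the same config are byte-identical.

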