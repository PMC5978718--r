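---
title: "Methods: genetically informed niche shifts and rates of phenotypic evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically informed niche shifts and rates of phenotypic evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When an invasive species is traced genetically to a restricted subregion of
its native range, the climatic niche comparison that matters is *source
versus invaded*, not *whole native range versus invaded*. Comparing against
the whole native range can understate a niche shift or even reverse its
apparent direction: a species sourced from the cold, seasonal end of its
native range that invades warm, mild coastlines looks like a cold-shifted
invader when the full native range is used, and a warm-shifted one when the
source subset is used. The direction of that shift, in turn, predicts which
phenotypes should have evolved during the invasion — populations occupying
*expansion* niche space (climates the source never occupied) are the ones
expected to show shifted stress tolerance, and the magnitude of tolerance
change over the invasion timescale can be expressed as a rate of phenotypic
evolution in darwins.

`nicheshift` implements this whole chain for coastal invaders assayed with
ordinal stress phenotypes (bleaching scores of a seaweed thallus being the
motivating case): climate ordination, kernel-density niche regions, the
Overlap / Expansion / Unfilled (O/E/U) classification, clone and ploidy
filtering of multilocus microsatellite genotypes, proportional-odds mixed
models for the ordinal assays, latitudinal cline analysis, and darwin-rate
estimation — together with a seeded synthetic-data generator that emulates
the entire data structure so the pipeline is testable end to end without
any external rasters or repositories.

# Niche-space construction

## Background and buffered extraction

The available coastal habitat is discretized as the centers of the 1° × 1°
half-open grid cells that any coastline polyline intersects
(`build_coastal_background()`; cells `[lon, lon+1) x [lat, lat+1)`, exact
incremental grid traversal, antimeridian-crossing segments split first).

Because any one climate layer may be undefined exactly at a coastal point
(a sea-surface layer over a land cell or vice versa), the environmental
value attached to a site is a *buffered average*: `extract_env()` samples
50 points area-uniformly within a 50-km great-circle disk (radius drawn as
`r = R * sqrt(u)`, bearing uniform, longitude offsets compressed by
`cos(lat)`, sphere radius 6371.0088 km) and averages the valid (non-nodata)
hits per variable; a variable with no valid hit at all is an error naming
the variable and site. Both the count and the radius are tunable; the
defaults reflect the scale at which coastal SST/SAT/salinity layers are
typically resolved.

## Correlation filter and ordination

Highly collinear climate variables carry no extra ordination information
and destabilize loadings, so variables are first filtered to pairwise
`|Pearson r| < 0.9` (`filter_correlated()`). Removal is greedy and
deterministic: repeatedly take the currently worst pair and drop the member
with the larger mean `|r|` against all remaining variables, breaking ties
by variable-name order.

`fit_pcaenv()` then fits a correlation PCA (center + unit scale) over the
*combined* background and occurrence rows. Two choices deserve comment:

* **Scaling** is not optional: the variables mix °C, mm and salinity units,
  so covariance PCA would be meaningless.
* **The fitting set** is background + occurrences jointly. Fitting on
  background only, or occurrences only, are defensible alternatives; the
  joint fit uses all available climate information and keeps every score a
  first-class projection. The choice is exposed through the function
  arguments (fit on any rows, project any others with `predict()`), so a
  background-only ordination is one call away.

Loading signs follow a fixed convention (the largest-magnitude loading of
each component is made positive) so that runs are bit-reproducible across
platforms and BLAS builds.

## Kernel-density niche regions and O/E/U

The niche region of a score cloud is the highest-density region of a
bivariate Gaussian kernel density estimate holding 99% of the
grid-normalized mass (`kde_region()`). Bandwidth is Scott's rule applied to
the full sample covariance, `H = n^(-1/3) * S`; the full-covariance form
matters because PC1/PC2 clouds of coastal climates are usually elongated
and tilted. The region is deterministic given the evaluation grid (default
200 × 200, padded three marginal bandwidths beyond the data range) and the
bandwidth; the recorded `threshold` makes the region reproducible and
resamplable. A point-degenerate cloud falls back to a small spherical
bandwidth so the region stays a compact neighborhood of the point rather
than an error.

`classify_niche()` is set algebra on two such regions evaluated on a shared
grid: cells in both are Overlap (O), invaded-only cells are Expansion (E),
native-only cells are Unfilled (U). Populations are classified by the cell
containing their population-level score (the mean of member-occurrence
scores); a population outside both regions is reported as `outside` rather
than silently forced into a class. `centroid_shift()` reports the arrow
between the mean native and mean invaded scores. Running the native side
with source-only occurrences versus all native occurrences is the
genetically informed versus naive comparison; both are one switch apart in
`niche_shift()`.

# Clone and ploidy filtering

Haplodiplontic seaweeds mix haploids, diploids and clonal ramets in one
sample, and phenotype analyses want one ramet per diploid genet. Ploidy is
called from microsatellite heterozygosity: at least one heterozygous locus
means diploid, otherwise haploid (`infer_ploidy()`). This is the standard
field rule and it has a known blind spot — a diploid homozygous at every
locus is called haploid; with ten loci of realistic diversity that event is
rare, and the package follows the rule verbatim rather than inventing a
correction.

Repeated multilocus genotypes (MLGs) are either clonal ramets or, for
common genotypes, plausible products of independent sexual events. The
discriminator is `Psex`: with `pgen` the Hardy–Weinberg probability of the
genotype (product over scored loci of `p^2` or `2pq` from per-population
allele frequencies), the probability that an MLG seen `n` times among `N`
sampled thalli arose sexually is the binomial tail
`sum_{j>=n} C(N,j) pgen^j (1-pgen)^(N-j)`. Repeats with `Psex < alpha`
(default 0.05, exposed) are flagged clones and all but the first ramet in
input order are dropped; repeats with large `Psex` are retained as
independent genets. Implementation decisions, all recorded in the function
documentation: the plain binomial formulation (no inbreeding-coefficient
correction); allele frequencies computed after one provisional round of
exact-duplicate collapsing so clonal ramets do not inflate their own
genotype frequencies (switchable); MLG matching over mutually scored loci
with a minimum of five shared loci to call two thalli the same genet
(conservative toward retaining genets).

# Ordinal phenotype models

The assay outcome is an ordinal Bleaching Score (1 none, 2 partial, 3
full); the analysis response is the Standardized Bleach Score
`SBS = BS_treatment - BS_control` in −2..2, and the population-level
display quantity is the proportion of thalli with `SBS > 0`
(`proportion_bleached()`).

`fit_clm()` and `fit_clmm()` are proportional-odds (cumulative-logit)
maximum-likelihood fits written for this package:

* cutpoints are kept ordered through the reparameterisation
  `theta_1 = zeta_1`, `theta_k = theta_{k-1} + exp(zeta_k)`;
* the fixed-effects model uses analytic gradients, a deterministic start
  (cumulative empirical logits, zero slopes) and a Newton polish to a
  gradient-norm tolerance of 1e-8, so fits are exactly reproducible;
* the mixed model adds a population random intercept
  `b ~ N(0, sigma^2)` integrated out by *adaptive* Gauss–Hermite
  quadrature: each population's nodes are centred at its conditional mode
  (found by a safeguarded joint Newton iteration across all populations at
  once) and scaled by the local curvature, with 15 nodes by default —
  the test suite asserts that moving to 25 nodes shifts the
  log-likelihood by less than 1e-4 on its fixtures, so 15 is comfortably
  inside the accuracy budget;
* the outer optimization is BFGS over `(zeta, beta, log sigma)` started
  from the fixed-effects fit with `sigma = 0.3`, using the
  posterior-weighted score (Fisher identity) as the analytic gradient.

The fit is validated in the test suite against three independent routes:
logistic regression (`glm`) for the two-category case, `MASS::polr` for
the fixed-effects proportional-odds case, and a from-scratch grid-search
likelihood maximizer for a small two-group dataset.

SBS enters the models over the ordered levels actually observed in the
analyzed subset — typically `{0, 1, 2}`, with negative control-exceeding
scores joining as the lowest categories when present. Collapsing negatives
into zero would be an alternative; fitting the observed levels avoids
discarding information and changes nothing when negatives are absent.

## The analysis-of-deviance battery

`deviance_table()` reproduces the region × treatment analysis: the full
model `SBS ~ region * level + (1 | population)` and likelihood-ratio rows
for (i) the random intercept (mixed versus fixed full model, 1 df, no
boundary correction — this is the common convention and is
anti-conservative, which is acceptable because the row is reported, not
used for selection), (ii) the overall model, and (iii) region, treatment
and interaction, each term's columns dropped from the full design. Post
hoc rows refit the region contrast within each treatment level (random
intercept retained by default; droppable). Raw p-values are reported with
no multiplicity correction. A region with a single population makes the
random-intercept row non-estimable; fixed rows are still returned, then
from fixed-effects fits.

`ove_contrast()` regresses SBS on the O/E niche label with the population
random intercept, after user-specified exclusions (e.g. coastlines whose
thalli are only partially traced to the genetic source). Note that O
populations include native-source populations — the contrast compares
occupants of overlap niche space with occupants of expansion niche space,
whichever range they belong to.

`cline_model()` is the ANCOVA-like latitudinal cline test: SBS on
population SSTmax (centred), region, and their interaction, with the
population random intercept, plus per-region predicted
bleaching-probability curves (`P(SBS > 0)` at random intercept zero) and
the per-coastline R² of SSTmax against |latitude| as a gradient
diagnostic.

# Darwin rates

`darwin_rate(x1, x2, years) = |ln(x2/x1)| / (years / 1e6)` — one darwin is
a factor-e change per million years. The trait entering the rate is the
population-group mean proportion bleached at one treatment level, floored
at `epsilon = 0.01` so ratios stay defined when a group never bleaches;
the floor, the 100-year invasion window, and the trait extractor itself
are all arguments, because the published convention fixes only the formula
and the averaging (arithmetic mean across invaded-coastline × treatment
cells per stressor, `rate_summary()`), not the trait summary.

# The synthetic world

The generator is first-class, tested code; its defaults define the study
conditions every downstream module is tested under.

* **Geometry**: one native meridional coastline (lat 31–45.5, a
  northwestern-Pacific analogue) whose *source band* spans 38–44° — the
  cold, seasonal end — plus three invaded coastlines (wNA, eNA, EU
  analogues). Population counts default to the study design the package
  mirrors: 15 native (6 source), 5 + 10 + 10 invaded.
* **Climate**: 13 layers (salinity; SST and SAT mean/max/min/range; four
  monthly precipitation layers) as linear latitudinal gradients plus
  seeded cell noise. Temperature layers fall with |lat|; seasonal-range
  layers rise with |lat|. Invaded coastlines receive a +3 °C temperature
  offset and a −4 °C seasonal-range offset, so the invasion extends into
  warmer, less seasonal climate space, exactly the structure whose
  recovery the niche-shift tests assert.
* **Genotypes**: 16 thalli per population at 10 microsatellite loci, with
  per-population Dirichlet allele frequencies and planted clone copies
  (default 25%) and haploids (default 10%), each recorded in a truth
  table. Unique diploids are redrawn on an exact-MLG collision or an
  all-homozygous draw, so planted genet identity is unambiguous and the
  clone-filter acceptance check can demand exact recovery.
* **Phenotypes**: a latent cumulative-logit model — exactly the model
  fitted downstream, which makes parameter recovery well-posed. Defaults:
  cutpoints (2.2, 4.0) placed so control bleaching is rare (the few
  negative SBS values that still occur are kept, matching their rarity in
  real assays; no censoring); invaded-region tolerance advantage −1.5
  latent units; SST slope −0.2 per °C; population random-intercept sd 0.5;
  severities rising with treatment level within each of the three
  stressors (heat 40 °C × 1/2/4 h, cold −20 °C × 45/75/105 min, salinity
  0/5/10 ppt). The control-condition bleaching distribution is a free
  parameter of the generator, not a claim about any real assay.
* **Seeding**: every stage derives a named child seed from one global
  seed; the same configuration is byte-identical across runs and no
  global RNG state leaks.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: real coastline geometry and spatial
autocorrelation of climate beyond the linear gradients; genotyping error,
null alleles and missing data patterns; linkage or inbreeding in allele
frequencies; assay-plate effects or observer error in bleaching scores;
and any form of plasticity versus adaptation distinction (the common-garden
stage label exists, but the generator draws both stages from the same
latent parameters unless told otherwise).

# Numerical choices and problem sizes

Tolerances: PCA eigenstructure is checked to 1e-8 on an exactly
constructed correlation; the fixed-effects ordinal fit is polished to
gradient norm 1e-8 and matches `glm`/`polr` log-likelihoods to 1e-6;
quadrature stability is asserted at 1e-4 between 15 and 25 nodes;
likelihood-ratio statistics are clamped at zero. The kernel-region
calibration uses 5,000 standard bivariate normal draws against the
analytic 99% ellipse area (within 15%, with point coverage at least 0.97).
Mixed-model recovery uses 50 replicates of 20 populations × 50
observations at β = 1.0, σ = 0.7 (mean recovery within 10%); test
calibration uses 1,000 null replicates (rejection rate in [0.03, 0.07]);
the end-to-end niche-phenotype pattern uses 100 seeded replicates with a
planted 1.5-latent-unit expansion advantage and a planted negative SST
cline (both recovered in at least 95 of 100). These sizes were chosen as
the smallest at which the corresponding statistical statements are stable,
and they are the sizes the test suite runs at.

# Known limitations

* The niche analysis is an ordination-overlap method; it does not fit an
  environmental niche model (MaxEnt-style), run niche equivalency
  permutation tests, or apply occurrence-density kernel weighting in
  climate space.
* Raster input is ESRI ASCII grid only; the format is plain text, lossless
  for this use, and readable/writable without any geospatial stack.
* `Psex` uses the plain binomial formulation without the
  inbreeding-corrected variant.
* The random-intercept LRT row is anti-conservative at the boundary (no
  half-chi-square mixture correction), as noted above.
* Darwin rates depend on the configured trait floor when a group's
  proportion bleached is zero; rates built from floored values should be
  read as order-of-magnitude statements.
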