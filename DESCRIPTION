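Package: nicheshift
Title: Genetically Informed Niche-Shift Analysis and Rates of Phenotypic
    Evolution for Coastal Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify climatic niche shifts of coastal invasive
    species relative to their genetically identified source populations, and
    to infer the phenotypic evolution those shifts predict. Builds a
    principal-component ordination of climate variables over coastal
    background and occurrence sites (PCAenv), delimits 99% kernel-density
    niche regions and classifies populations into Overlap, Expansion and
    Unfilled niche space, filters clonal replicates and haploids from
    multilocus microsatellite genotypes via Psex, fits proportional-odds
    cumulative-link models (with population random intercepts integrated by
    adaptive Gauss-Hermite quadrature) to ordinal bleaching scores, tests
    latitudinal tolerance clines against sea-surface temperature, and
    converts tolerance change over the invasion timescale into darwins. A
    seeded synthetic-data generator emulates coastlines, climate layers,
    occurrences, genotypes and ordinal phenotypes so the full pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    geosphere,
    optparse
Config/testthat/edition: 3
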