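Package: msatpop
Title: Microsatellite Population Genetics and Phylogeography Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete pipeline for diploid microsatellite population
    genetics: genotype ingestion (GENEPOP, STRUCTURE two-row, long CSV),
    per-locus diversity summaries (allele counts, rarefied allelic richness,
    PIC, heterozygosities), Weir-Cockerham F_ST with permutation tests and
    island-model gene flow, between-population molecular coancestry, Nei's
    standard distance and Goldstein's (delta-mu)^2 distance with locus
    bootstrap, neighbor-joining trees with bootstrap supports, divergence
    time calibration under the stepwise mutation model, admixture-model
    Bayesian clustering with Evanno's Delta-K model selection, DAPC, and a
    forward-time Wright-Fisher simulator of microsatellite genotypes under
    the stepwise mutation model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
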