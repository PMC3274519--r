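Package: mitopop
Title: Mitochondrial Phylogeography and Population Demography Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis chain for single-locus (mitochondrial)
    phylogeographic data sets: haplotype collapsing and site classification,
    Kimura 2-parameter distances, haplotype and nucleotide diversity,
    median-joining haplotype networks with weighted substitution classes and
    maximum-parsimony (Steiner) pruning, hierarchical analysis of molecular
    variance (AMOVA) with permutation tests, pairwise Fst, mismatch
    distribution analysis under the sudden-expansion model, Fu's Fs and
    Ramos-Onsins & Rozas's R2 neutrality tests with coalescent null
    distributions, and expansion-time dating from a divergence-calibrated
    substitution rate. Ships a coalescent simulator (constant size, sudden
    expansion, population splits; finite-sites transition-biased mutation)
    used for synthetic data, null distributions and parametric bootstraps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
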