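Package: hybridkit
Title: Multilocus Detection of Hybridization and Introgression in Wild Canids
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting wolf x dog hybrids and introgressed individuals
    from panels of autosomal microsatellites combined with uniparental (mtDNA
    control-region, Y-linked microsatellite) and diagnostic coat-colour
    (beta-defensin CBD103 K-locus) markers. Provides readers for Structure and
    Genepop genotype files; diversity, Hardy-Weinberg, linkage and
    probability-of-identity statistics; Weir-Cockerham F_ST and distance-based
    AMOVA (PhiPT); Queller-Goodnight relatedness; F_ST-based marker-panel
    ranking and nested panel construction; a Balding-Nichols synthetic-population
    generator and HybridLab-style simulation of F1/F2/backcross genotype classes;
    a Bayesian admixture Gibbs sampler with popflag-anchored reference clusters,
    Ln P(D) and Delta-K model choice; Rannala-Mountain assignment, six-class
    hybrid-category posteriors, iterated-reallocation partitioning and
    empirical-null admixture significance tests; threshold calibration, detection
    power and false-positive analyses across panel sizes; and a rule-based
    consensus classifier that integrates all lines of evidence into final
    hybrid-class identifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
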