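Package: NAMtools
Title: Simulation and Mixed-Model Association Analysis of Nested
    Association Mapping Populations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of multi-family
    nested association mapping (NAM) populations of recombinant inbred
    lines, modelled on the 40-family soybean NAM design. Provides a
    synthetic-population generator (homozygous founder panels, single-seed
    descent under the Haldane map function, augmented incomplete-block
    multi-environment trials), marker filtering and RIL quality control
    with dense-marker projection, two-stage mixed-model BLUP analysis of
    plot data with broad-sense heritability on harmonic-mean replication,
    a family-nested random allele-substitution genome scan with a
    VanRaden genomic relationship matrix and linkage-window exclusion,
    and 5-cM binning of marker-trait associations with allele-effect
    pattern classification and founder-group summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    yaml,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
biocViews: Genetics, GenomeWideAssociationStudy, SNP, Regression,
    LinkageDisequilibrium
Config/testthat/edition: 3
RoxygenNote: 7.3.3
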