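Package: invagen
Title: Population Genomics and Host-Plant Use of Invasive Insect Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for characterising recently introduced
    insect populations from reduced-representation SNP data and field host
    surveys. Provides VCF-based genotype filtering (biallelic, missingness,
    depth, minor allele frequency, linkage-disequilibrium pruning), per
    population diversity statistics (expected and observed heterozygosity,
    rarefied allelic richness, private alleles, inbreeding coefficient with
    bootstrap intervals, windowed Tajima's D), Weir-Cockerham pairwise FST,
    principal component and admixture-style (sparse nonnegative matrix
    factorisation) structure analysis with cross-entropy choice of K,
    single-population coalescent demographic inference on the folded site
    frequency spectrum (constant, bottleneck, bottleneck-plus-growth and
    full bottleneck models) with composite-likelihood Brent-cycle fitting,
    AIC model selection and parametric bootstrap confidence intervals,
    Neu-method resource-selection analysis of host-plant attack with
    Bonferroni simultaneous intervals, and Schoener's D / Hellinger's I
    niche-overlap indices. A seeded synthetic-data module generates every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    deSolve,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
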