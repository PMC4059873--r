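Package: BinMapQTL
Title: Bin-Map Construction and QTL Mapping for Low-Coverage F2 Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an end-to-end analysis for ultra-low-coverage
    genotyping-by-sequencing of F2 intercross populations: sliding-window
    genotype calling over sparse parental-allele observations, inference of
    genotype blocks and recombination breakpoints, construction of a
    population-level recombination bin map on a 100-kb grid, segregation
    filtering, genetic-map estimation with Haldane's map function via
    two-point EM recombination fractions, and single- and multiple-QTL
    genome scans with permutation-based significance thresholds, 1.5-LOD
    support intervals and additive/dominance effect decomposition. Includes
    a synthetic-population generator that emulates the sparse single-read
    allele sampling of low-coverage GBS, with full ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, QualityControl
RoxygenNote: 7.3.3
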