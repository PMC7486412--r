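Package: germdiv
Title: Genebank Germplasm Diversity Analysis for Structured Crop Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing genetic diversity in large genebank
    collections genotyped with biallelic SNP and dominant presence/absence
    markers. Implements marker and sample quality-control filters,
    genome-fraction ploidy checks, diversity indices (expected and observed
    heterozygosity, inbreeding coefficient, Shannon index), Modified Rogers
    and Jaccard pairwise distances, classical and SMACOF multidimensional
    scaling, iterative hierarchical clustering with pseudo-F profiles, Nei's
    AMOVA/FST with permutation significance and windowed selection-footprint
    scans, D-method core-subset construction, and consensus genetic-map
    merging. A synthetic-data module generates structured collections with
    known drift, sweeps, ploidy misclassification and distorted linkage maps
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
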