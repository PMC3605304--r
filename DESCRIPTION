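Package: PGxStar
Title: Star-Allele Calling and Activity-Score Phenotype Prediction for
    CYP2D6 and CYP2C19
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacogene star-allele (haplotype) assignment from
    per-sample variant calls, integrating gene deletion/duplication (CNV)
    evidence and exon-9 gene-conversion assays; Activity-Score based
    metaboliser phenotype prediction (PM/IM/EM/UM) under both additive
    Activity-Score thresholds and categorical array-style rules; cohort
    population-genetics summaries (stratified allele frequencies, exact
    Hardy-Weinberg tests, Fisher's exact tests, pairwise linkage
    disequilibrium with EM haplotype-frequency estimation); and a synthetic
    cohort simulator with parametrised genotyping-platform error models
    (allele miscall maps, deletion dropout, assay failure) so that every
    stage of the pipeline can be exercised and benchmarked without access
    to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, Genetics, SNP, Pharmacogenetics, Pharmacogenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
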