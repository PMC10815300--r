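Package: snapAge
Title: Epigenetic Age Estimation from SNaPshot Methylation Peak Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating human chronological age from buccal-swab
    DNA methylation measured by bisulfite conversion, multiplex single-base
    extension (SNaPshot) and capillary electrophoresis at five age-associated
    loci (ELOVL2, FHL2, KLF14, C1orf132/MIR29B2C, TRIM59). Reads
    capillary-electrophoresis peak tables, converts methylated/unmethylated
    peak intensities to methylation levels, checks bisulfite-conversion
    controls and between-conversion homogeneity, averages the 2x2
    conversion-by-amplification replicates, fits or applies multivariate
    linear age models (including a published five-locus buccal-swab model),
    and evaluates predictions by mean absolute deviation overall and by age
    group, per-locus Pearson correlation and R-squared. A seeded synthetic
    cohort and peak-table generator emulates the replicate design so the
    whole pipeline can be exercised without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Regression, QualityControl
RoxygenNote: 7.3.3
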