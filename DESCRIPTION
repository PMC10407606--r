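Package: rootgwas
Title: Adventitious Root Phenomics and Association Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for image-based phenotyping of
    adventitious roots and genome-wide association mapping of the resulting
    traits. Provides a synthetic scene and genotype/phenotype panel
    generator with exact ground truth, palette-based scene and tissue
    segmentation, per-root geodesic length and area measurement with metric
    calibration, genotype-level trait tables with Box-Cox and rank-based
    inverse-normal transformations and SNP-heritability gating, mixed-model
    Wald scans, logistic mixed-model score scans for binarized traits,
    windowed SNP-set kernel association tests (SKAT) with adaptive
    Monte-Carlo empirical p-values, augmented rank truncation combination of
    single-SNP p-values over windows, and QTL peak calling with
    nearest-gene annotation from GFF3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    grDevices,
    png,
    jsonlite,
    igraph,
    EBImage,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
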