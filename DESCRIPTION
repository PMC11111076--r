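Package: fundusGWAS
Title: Self-Supervised Image Phenotyping and Mixed-Model GWAS of Retinal
    Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of image-based
    genome-wide association: a procedural simulator of genotypes and paired
    left/right retinal fundus images with known causal structure; an image
    quality scorer; a self-supervised contrastive phenotyper trained with an
    additive angular-margin (ArcFace-style) template loss that embeds both
    eyes of a subject nearby on the unit sphere; retina-color phenotype
    extraction from the central foveal patch; an exact linear-mixed-model
    association engine (REML variance components by eigendecomposition of
    the genetic relationship matrix, generalized-least-squares Wald tests,
    leave-one-chromosome-out); and post-processing: dual-eye intersection
    replication, LD-based locus clumping, LD scores, simplified LD-score
    regression for heritability and genetic correlation, and local catalog
    range queries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    EBImage,
    png,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
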