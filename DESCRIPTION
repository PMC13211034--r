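Package: grainQTL
Title: Grain Counting from Barley Spike Images and QTL Mapping in
    Doubled-Haploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: An end-to-end phenotype-to-QTL workflow for grain number per
    spike in two-rowed barley doubled-haploid (DH) populations. Provides a
    classical image preprocessing chain (HSV colour masking, Otsu
    thresholding, morphological refinement, convex-hull masking) that
    isolates spikes from dark or cluttered backgrounds, connected-component
    grain counting with detector-agreement statistics, plot-level phenotype
    quality control (replicate CV, repeatability, outlier-median rule,
    row-column REML variance components and broad-sense heritability), and
    a single-QTL genome scan stack: a two-state genotype-probability HMM
    with genotyping error, Haley-Knott regression, LOCO-kinship linear
    mixed models, principal-component structure correction, permutation
    LOD thresholds, nested-model ANOVA and allele-effect statistics. A
    synthetic-data module simulates genetic maps, DH genotypes, partially
    replicated field designs, phenotypes with planted QTL, detector count
    errors and rendered spike images with exact ground truth, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    lme4,
    jsonlite,
    png,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'grainQTL-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'simulate-map.R'
    'simulate-genotypes.R'
    'simulate-field.R'
    'simulate-phenotypes.R'
    'simulate-counts.R'
    'simulate-image.R'
    'image-pipeline.R'
    'grain-metrics.R'
    'phenotype-qc.R'
    'qtl-genoprob.R'
    'qtl-kinship.R'
    'qtl-scan.R'
    'qtl-structure.R'
    'qtl-perm.R'
    'qtl-effects.R'
    'candidate-interval.R'
    'io.R'
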