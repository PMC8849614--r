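Package: rosetteqtl
Title: Rosette Shape Morphometry and Multiparent QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify Arabidopsis rosette morphology from binary
    top-view masks and to map the genetic basis of shape in a multiparent
    (MAGIC) population. Computes nine classical shape descriptors (projected
    area, perimeter, compactness, rotational mass symmetry, slenderness of
    leaves, roundness, convex-hull roundness, isotropy, eccentricity) from
    rasters via contour tracing, convex hulls, image moments and morphological
    skeletonization; summarises replicated longitudinal phenotypes (replicate
    averaging, per-day Pearson correlations, broad-sense heritability by
    one-way variance decomposition, a correlation-matrix PCA morphospace);
    reconstructs founder-of-origin probabilities along recombinant inbred
    genomes with a hidden Markov model and scans each marker with a 19-founder
    association model, using permutation-based genome-wide thresholds;
    post-processes scans into peak/interval calls, a day-then-descriptor
    redundancy filter, summary tabulations and nearest-gene annotation.
    A synthetic-data module generates rosette masks with analytically known
    descriptors and simulates MAGIC-like populations with planted QTLs so the
    whole pipeline is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    lme4,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    rtracklayer,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
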