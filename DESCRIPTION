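Package: svrfa
Title: Multivariate Support Vector Regression Mapping of White Matter
    Fractional Anisotropy and Structural Disconnection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate lesion-symptom mapping on tract-based
    fractional anisotropy (FA) skeletons: a linear-kernel support vector
    regression relates voxel-wise skeletonized FA to a behavioural score,
    hyperparameter C is selected by cross-validated model fit and
    feature-weight reproducibility, and voxel-wise significance is assigned
    by label-permutation testing with Benjamini-Hochberg false discovery
    rate control and minimum-cluster-extent filtering. The significant-voxel
    map is then quantified as a structural disconnectome by intersecting a
    whole-brain tractogram with the map and counting affected streamlines
    per parcellated region pair, and referenced to probabilistic tract
    atlases by thresholded-overlap volumes. A synthetic phantom cohort
    generator (skeleton, parcellation, spherical lesions that depress FA,
    a planted voxel-to-behaviour effect, and tractograms with known
    region-pair counts) provides a fully ground-truthed test bed, and
    cohort-level descriptive statistics (chi-square, Mann-Whitney U,
    two-sample t, correlations) round out the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    kernlab,
    igraph,
    tibble,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
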