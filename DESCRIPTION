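Package: vasculomorph
Title: Quantification of Cerebrovascular Angioarchitecture from Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Vasculomorph", "Developers", email = "maintainers@vasculomorph.dev",
           role = c("aut", "cre"))
Description: A tested re-implementation of a Fiji-plugin-based pipeline for
    quantifying cerebrovascular angioarchitecture in vessel-painted cortical
    fluorescence images. Provides image preparation (z-projection, polygon ROI
    extraction, auto-contrast, sharpening, morphological haze reduction,
    binarization), multiscale Hessian vessel segmentation with whole-field
    network metrics (vessel density, junction density, average vessel length),
    box-counting fractal analysis with local fractal dimension histograms and
    their summary features, semi-automated live-wire centerline tracing,
    topology-preserving skeletonization with endpoint/junction/slab tagging,
    branch-graph measurement including the tortuosity index, collateral-vessel
    analysis, group-comparison statistics (one-way ANOVA with Tukey, two-way
    ANOVA with Sidak, covariance ellipses), and a synthetic vascular image
    generator with analytic ground truth used as the test oracle throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
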