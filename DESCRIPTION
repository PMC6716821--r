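Package: dtipipe
Title: Longitudinal Diffusion Tensor Imaging Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A cohort-level pipeline for longitudinal diffusion tensor
    imaging (DTI) studies in the mouse brain: log-linear tensor fitting with
    fractional anisotropy (FA), axial (AD), radial (RD) and mean (MD)
    diffusivity maps; iterative study-specific template construction and
    stereotaxic normalization onto a 50 micrometre isogrid; whole
    brain-based spatial statistics (WBSS) with voxelwise t-tests,
    false-discovery-rate and cluster-size correction; per-day longitudinal
    rate-of-change maps; deterministic streamline tractography with
    tractwise fractional anisotropy statistics (TFAS); spherical-ROI
    analysis; and a two-way ANOVA with Tukey post-hoc tests computable from
    per-cell summary statistics. Ships a synthetic diffusion-weighted
    cohort simulator with known tensor ground truth so every stage is
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
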