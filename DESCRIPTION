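Package: safmap
Title: Mapping and Validating Short Association Fibre Connectivity in
    Retinotopic Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to map and statistically validate short association
    fibre (U-fibre) connectivity between retinotopically organised visual
    areas V1, V2 and V3. Implements surface-based smoothing of eccentricity
    and polar-angle phase maps with a signal-to-noise gate, automated
    segmentation of each visual area into six retinotopic sub-areas,
    simplified probabilistic fibre-ODF and isotropic null-field
    tractography, streamline-to-surface connection assignment with an
    intracortical-length filter, 18x18 streamline-count, percent and
    closeness connectivity matrices, a retinotopic-order ratio, and
    one-tailed Poisson and paired t significance tests against null
    tractography with sensitivity/specificity summaries. A synthetic-cortex
    module generates folded surface meshes, retinotopy maps, fibre-ODF
    fields and planted tractograms so the entire pipeline can be exercised
    and validated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
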