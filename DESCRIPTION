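Package: deepangio
Title: Quantification and Quality Control of Deep Capillary Plexus OCT
    Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing en-face optical coherence tomography
    angiography (OCT-A) images of the retinal deep capillary plexus (DCP)
    in diabetic eyes. Provides artifact-aware quality control (projection,
    motion, blur, signal loss, poor centration, low device quality score),
    quantification of foveal avascular zone area, parafoveal vessel
    density and box-counting fractal dimension, test-retest reliability
    via intraclass correlation coefficients, and a clustered
    (fellow-eye) association workflow based on linear generalized
    estimating equations with per-SD standardized predictors. A synthetic
    data module generates vortex-textured DCP angiograms, superficial
    plexus images with large vessels, injected artifact classes, and
    clinical cohorts with known effect sizes, so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    igraph,
    jsonlite,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
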