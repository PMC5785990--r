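Package: octhaze
Title: Vitreous Haze Quantification from OCT B-Scans and
    Acquisition-Parameter Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies vitreous haze on optical coherence tomography (OCT)
    B-scans as the vitreous/RPE-relative intensity (VRI): the mean intensity
    of an automatically generated vitreous patch divided by the mean
    intensity of the segmented retinal pigment epithelium (RPE). Includes a
    synthetic OCT phantom and study simulator emulating frame averaging
    (ART), focus offset and vertical positioning effects with a nested
    random-effects structure; morphological-opening retina/RPE segmentation
    with failure detection; and the variability analysis: linear mixed
    models with nested random effects for setting effects on the mean VRI,
    three-level residual decomposition (within-scan, intra-subject,
    inter-subject), Gamma generalized linear models with a log link on
    squared residuals for variability, and Tukey-adjusted pairwise
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    emmeans,
    jsonlite,
    lme4,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
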