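Package: sdwave
Title: Detection and Hemodynamic Characterization of Spreading
    Depolarizations in Multimodal Cortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spreading depolarizations (SDs) recorded
    after cerebral venous occlusion with DC-coupled electrocorticography
    (ECoG), intrinsic optical signal (IOS) imaging and laser speckle contrast
    imaging (LSCI).  Detects propagating slow potential changes with
    depression of spontaneous activity in multichannel ECoG, applies the
    two-ROI rule to optical intensity traces, decomposes SD hemodynamic
    responses into vasomotor components I-V, classifies the four canonical
    response morphologies, quantifies monophasic CBF elevations with
    oxy-/deoxyhemoglobin coupling, and aggregates incidence, expansion and
    first-versus-last response statistics with exact rank tests.  A synthetic
    cohort generator simulates post-occlusion recordings with full ground
    truth, including a replication preset whose roster encodes a published
    swine study's cohort statistics by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
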