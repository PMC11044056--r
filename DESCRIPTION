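Package: adhesio
Title: Focal Adhesion Morphometrics, Biosensor Dynamics, and Kinase
    Substrate Screen Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for focal adhesion (FA) biology:
    segmentation and morphometrics of FAs from fluorescence images
    (median filter, rolling-ball background subtraction, mean-multiple
    thresholding, particle analysis), polar unwrapping and radial
    distribution comparison by two-sample Kolmogorov-Smirnov tests;
    pixel-based colocalization statistics (Pearson correlation, Li's
    intensity correlation quotient, Manders overlap) and FA-masked
    ratiometric images; ratiometric PKA-biosensor time-lapse analytics
    (FA tracking, ratio series with boxcar smoothing, sub-FA kymographs,
    peak-location scoring, growth-state classification, activity-by-state
    summaries); and kinase-catalyzed-biotinylation screen analytics
    (control filtering, per-trial fold enrichment, N-of-M-trials hit
    calling, PKA consensus phosphosite motif scanning). A synthetic-data
    generator with known ground truth makes every stage testable without
    microscopy or proteomics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
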