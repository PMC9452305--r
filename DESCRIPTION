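Package: viscmap
Title: Analysis of Volumetric Calcium Imaging of Visceral Sensory Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-photon calcium imaging of
    brainstem interoceptive neurons: nucleus ROI detection by normalized
    cross-correlation, fluorescence extraction, detrended dF/F computation,
    threshold-based mechanical and chemical response calling with
    frame-persistence criteria, k-means classification of adaptation
    kinetics, organ-tuning and selectivity profiling, stimulus-pair
    correlation structure, permutation-normalized spatial segregation
    statistics, enrichment indices, and paired-stimulus cross-inhibition
    (suppression) classification. Includes a synthetic-data generator that
    emulates a volumetric nucleus-of-the-solitary-tract (NTS) imaging
    experiment with known ground truth, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
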