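Package: liposort
Title: Simulated Image-Based Screening and Sorting of Gene-Expressing Liposomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An in-silico reimplementation of an image-based phenotypic
    screening and sorting workflow for gene-expressing liposomes (synthetic
    cells). Generates ground-truth vesicle populations and synthetic
    multi-channel confocal images and time-lapse videos, detects and
    classifies liposomes by membrane-versus-lumen reporter localization,
    tracks them across frames to call dynamic Min-protein oscillations,
    simulates photoactivation tagging with an off-target model and FACS
    recovery/gating, and quantifies library enrichment by qPCR standard
    curves and amplicon variant counting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Biostrings,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
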