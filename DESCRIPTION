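Package: epiquant
Title: Quantitative Histomorphometry of Regenerated Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative histology and semi-quantitative immunofluorescence
    analysis of skin-section images: basal-keratinocyte nuclear polarity
    measured against the dermo-epidermal junction, detection and scoring of
    non-cohesive (expanded intercellular) spaces within the epidermis,
    DAPI-normalized marker levels and positive-cell fractions, abnormal
    section-length morphometry with threshold classification of xenografts,
    and nonparametric cohort comparison. Includes a synthetic skin-section
    generator with exact ground truth so the whole pipeline is testable
    without real slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
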