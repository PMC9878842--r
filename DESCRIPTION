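Package: pcpquant
Title: Quantification of Epidermal Planar Cell Polarity from Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification toolkit for epidermal planar cell polarity
    (PCP). Classifies hair-follicle polarity and growth angle from two-marker
    (P-cadherin / Sox9) images, computes per-cell nematic order of
    membrane-localized proteins from label masks, scores junctional enrichment
    from ROI definitions, and fits FRAP recovery traces to a one-phase
    association model with immobile-fraction estimation. Ships a synthetic-data
    generator that produces every input type with known ground truth, so each
    estimator is validated by recovery tests against simulated tissue.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
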