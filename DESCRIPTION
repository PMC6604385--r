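Package: elfpipe
Title: Exposure, Location and Lung Function: Personal Exposure Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for week-long personal exposure studies that pair
    GPS time-activity traces, daily silicone-wristband PAH chemistry and
    hand-held spirometry. Implements per-fix spatial exposure estimators
    (nearest-monitor PM2.5, inverse-distance-weighted point-source emissions,
    road length and NDVI-by-land-class buffers, wildfire smoke density and
    proximity) with time-weighted daily aggregation; ATS-style spirometry
    quality control with percent-predicted FEV1 from NHANES III reference
    equations; wristband compliance filtering, half-LOD nondetect substitution
    and blank/surrogate correction with batch QC; study-level compliance and
    correlation reporting; and a fully seeded synthetic-cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    geosphere,
    MASS,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
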