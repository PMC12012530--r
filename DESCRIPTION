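Package: cortiscale
Title: Allometric Scaling and Multivariate Morphometry of the Neonatal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates allometric scaling coefficients of cortical surface
    area, thickness, and folding from per-subject morphometric tables;
    decomposes cortical morphology into orthogonal offset, isometric, and
    shape terms derived from the universal cortical folding law; compares
    groups and demographic effects with permutation-tested linear models
    under Holm family-wise error correction; and scores individual deviance
    from a normative control model to relate cortical morphology to early
    childhood neurodevelopmental outcomes. Includes a synthetic cohort
    generator so the full pipeline is testable without access to raw data,
    a global linear-model assumption check, and a high-breakdown fast-S
    robust regression fallback.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car
Config/testthat/edition: 3
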