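Package: biosimtier
Title: Tiered Analytical Similarity Assessment for Biosimilars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Risk-based criticality assessment and tiered statistical
    similarity testing for biosimilar quality attributes. Implements risk
    ranking and filtering (RRF) of quality attributes into critical quality
    attributes (CQAs), rule-based assignment of attribute/assay pairs to
    similarity tiers, and the three tier-specific comparison procedures:
    equivalence testing by two one-sided tests against a margin of
    1.5 reference standard deviations, a quality-range rule of reference
    mean plus or minus 3 standard deviations with a 90%-of-lots criterion,
    and a reproducible descriptive range comparison. Includes a Monte-Carlo
    operating-characteristics simulator for the tier-1 and tier-2
    procedures, a seeded synthetic lot-data generator emulating a
    6-versus-10-lot adalimumab biosimilar glycan comparison, and
    command-line entry points with CSV and markdown reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
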