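Package: cardioage
Title: Biological Cardiovascular Age from Structured Coronary CTA Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a heuristic biological cardiovascular age (BioAGE) from
    structured coronary CTA report metrics (coronary artery calcium score,
    CAD-RADS stenosis category, high-risk anatomy and left-ventricular
    function), evaluates its discrimination of major adverse cardiovascular
    events (MACE) against chronological age with ROC/AUC and DeLong
    confidence intervals, and ships a seeded synthetic cohort and report
    generator (German/English templates, parse-hostile variants) plus a
    deterministic rule-based report parser so the whole analysis runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
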