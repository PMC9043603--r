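Package: revdose
Title: Physiologically Based Pharmacokinetic Modeling and Reverse Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for generalized physiologically based
    pharmacokinetic (PBPK) modeling and in vitro to in vivo extrapolation
    (IVIVE). Provides a flow-limited multi-compartment model for forward
    dosimetry (tissue concentration time-series, Cmax, AUC) under arbitrary
    oral or intravenous dosing schedules, and Cmax-based reverse dosimetry
    that converts in vitro AC50 bioactivity concentrations into equivalent
    administered doses (EADs) and margin-of-exposure screening metrics.
    Chemical parameters are resolved from measured, predicted, or default
    sources with full provenance tracking; tissue:plasma partition
    coefficients are derived from tissue composition or supplied directly.
    Includes synthetic-fixture generators for testing complete workflows
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
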