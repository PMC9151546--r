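Package: mnscreen
Title: Hazard Classification and Risk Prioritization for High-Throughput
    In Vitro Micronucleus Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative interpretation pipeline for flow-cytometric in
    vitro micronucleus (MNvit) screens run in multi-well plates across a wide
    concentration range. Provides plate-table ingestion and quality control
    with batch-specific solvent-control reference percentiles, per-well
    endpoint arithmetic (percent micronucleated and hypodiploid cells,
    relative survival, fold change, cytotoxicity categories), a decision-tree
    hazard classifier for clastogenicity and aneugenicity built on the
    Jonckheere-Terpstra trend test and benchmark-concentration (BMC) modeling
    with the EFSA model-5 Hill and Exponential families, in vitro-to-in vivo
    extrapolation (IVIVE) of BMCs to administered equivalent doses via a
    three-compartment steady-state toxicokinetic model, and bioactivity
    exposure ratio (BER) ranking against human exposure estimates. A
    plate-structured synthetic-study generator with known ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
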