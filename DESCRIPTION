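Package: ecosoc
Title: Group Sociability Statistics, Composite Behavioral Scoring and
    Gene-Set Overlap for RFID Home-Cage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs per-animal compartment occupancy from RFID
    antenna-crossing events recorded in a four-compartment ring habitat,
    computes pairwise in-cohort sociability (observed minus expected
    co-occupancy under independent compartment preferences), approach to a
    social odor relative to a baseline dark phase, closed-form per-animal
    assay measures (three-chamber social preference index, marble-burying
    counts, IntelliCage percent-correct and sucrose preference,
    delta-delta-Ct fold change), a composite autistic-like score on [0, 3]
    built from min-max standardized behavioral domains, and gene-set overlap
    enrichment (representation factor and exact log-space upper-tail
    hypergeometric probability).  A continuous-time Markov simulator of
    group-housed mice with tunable pairwise social affinity generates
    synthetic antenna events with ground truth, so every stage of the
    pipeline is testable without proprietary raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
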