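Package: tadbound
Title: TAD Boundary Detection and Boundary-Factor Enrichment Analysis for Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for studying chromatin-factor enrichment at
    topologically associating domain (TAD) boundaries. Provides ICE matrix
    balancing, distance-decay expected models and observed/expected transforms,
    A/B compartment calling from the first principal component of the Pearson
    correlation map, TopDom-style TAD boundary detection with insulation and
    domain scores, between-condition TAD classification (invariant, merged,
    split, disappeared, rearranged), peak-to-boundary annotation and
    boundary-associated factor (baRBP-style) calling, non-negative matrix
    factorization consensus clustering of factor co-occupancy at cis-regulatory
    elements, aggregate domain analysis and boundary pile-ups, and
    transcription-boundary association statistics. A synthetic-data generator
    with planted ground truth (TADs, compartments, factor peaks, signal tracks)
    makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
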