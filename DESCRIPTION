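Package: indexleak
Title: Index Mis-Assignment Quantification for Multiplexed Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification of sample index mis-assignment
    (index hopping, oligo synthesis cross-contamination, PCR template
    switching, spot-array signal bleeding and sequencing error) in
    multiplexed short-read sequencing runs. Provides barcode-set design and
    validation under hamming-distance, GC and homopolymer rules; a synthetic
    read generator with per-mechanism ground truth, a pooling-stage switch
    and a linear (rolling-circle) versus exponential amplification model;
    quality-filtered demultiplexing; amplicon-panel read assignment; index
    by target contamination matrices with the rate conventions used for
    control, PCR-free and two-step PCR libraries; spatial neighbor-sharing
    analysis; and UID (unique molecular identifier) deduplication with
    mutant allele-rate calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
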