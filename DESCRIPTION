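Package: minigeneACMG
Title: Minigene Splicing Readout Quantification and ACMG/AMP Point-Based
    Variant Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns minigene splicing-assay readouts of candidate spliceogenic
    variants into ACMG/AMP point-based clinical classifications. Provides a
    transcript gene model with HGVS c. coordinate arithmetic (including
    intronic offsets), a parser for the compact splice-transcript annotation
    grammar (exon skipping, intronic inclusion, acceptor/donor shifts),
    reconstruction of mature mRNAs with frame, premature-termination-codon and
    nonsense-mediated-decay prediction, quantification of fluorescent
    capillary-electrophoresis peak tables into transcript fractions with
    replicate statistics, per-transcript evidence assignment and aggregation
    of complex readouts into PVS1_O/BP7_O codes, the rarity code PM2, a
    Bayesian point-sum classifier, a MaxEntScan-based candidate pre-filter,
    and a seeded synthetic-data generator so every stage is testable without
    external downloads. Ships a RAD51C exon 2-8 minigene fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
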