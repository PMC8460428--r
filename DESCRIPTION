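Package: segmentHomology
Title: Homology Segment Analysis of Ectopic Chromatin Pairing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links short-fragment DNA homology to ectopic pairing of
    polytene chromosome bands. Extracts all length-k fragments from a
    source genomic region, localizes their exact ungapped matches along a
    target chromosome on either strand, aggregates hits into per-band
    localized fragment frequency (LFF) profiles, and rank-correlates LFF
    with cytologically measured frequencies of ectopic contacts (FEC).
    Also provides per-fragment occurrence reports with simple-repeat and
    self-complementarity annotation, a reciprocal-cross classifier of FEC
    mode of inheritance based on a two-sample t criterion, locomotion
    quantization and courtship-learning statistics with a randomization
    test, and seeded synthetic-data generators (genome with planted repeat
    families, band maps, FEC tables, trajectory tracks, courtship samples)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
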