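Package: nclscreen
Title: Post-Screening of Non-Co-Linear Transcript Events from Multiple
    Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Harmonizes circular, trans-spliced and fusion RNA junction
    calls reported by multiple RNA-seq detectors onto annotated exon
    boundaries, flags likely false positives arising from ambiguous
    alignments of the junction-flanking sequence (alternative co-linear
    explanations and multi-locus hits), and scores every event's
    cross-tool reliability (tau, NCL score) and expression context (NCL
    ratio, circular fraction, co-linear junction usage, RPM). Includes a
    self-contained synthetic fixture generator with planted ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
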