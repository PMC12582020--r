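Package: nanotrna
Title: Nanopore tRNA-Seq Quantification and Modification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for nanopore direct RNA sequencing of
    transfer RNAs. Builds a deduplicated, adapter-padded tRNA alignment
    reference with Sprinzl position maps; recalibrates mapping quality from
    alignment-score gaps between primary and alternative hits (MOD-MAPQ) and
    assigns multi-mapping reads to anticodons via same-target / same-codon
    rescue; produces per-anticodon expression matrices with fixed-sum
    normalization and mapping QC; infers candidate modification sites from
    per-position base-calling error statistics (relative error, reference
    base fraction, condition log2 ratios, per-Sprinzl-position tests);
    filters and compares modkit bedMethyl modification pileups against
    orthogonal site tables; and ships a fully deterministic synthetic-data
    generator so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
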