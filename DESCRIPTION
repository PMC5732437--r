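Package: ampliCall
Title: Amplicon Variant Calling with Phased MNPs and HGVS Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: A single-command pipeline for clinical amplicon sequencing
        panels: merges overlapping read pairs into consensus reads,
        assigns them to amplicons by primer matching, calls variants by
        Smith-Waterman alignment against the amplicon references, phases
        proximate in-phase variants into compound delins (MNP) records,
        normalizes every call to its most parsimonious 3'-shifted HGVS
        representation (g., c. and p.) against a preferred RefSeq-style
        transcript, annotates calls from a pluggable attribute backend,
        and writes an annotated VCF plus an optional tab-separated
        variant table. Includes a synthetic panel and read simulator so
        the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Biostrings, IRanges, GenomicRanges,
        S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), VariantAnnotation, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
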