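Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tag-based digital transcript abundance
    (DTA/DGE) profiling experiments of the NlaIII/MmeI type. Extracts virtual
    CATG-anchored 21-mer tags from a reference transcriptome, cleans raw tag
    libraries, maps clean tags with at most one mismatch while discarding
    ambiguous hits, normalizes counts to transcripts per million clean tags
    (TPM), and identifies differentially expressed tags and unigenes with the
    Audic-Claverie exact test under Benjamini-Hochberg false discovery rate
    control. Also provides delta-delta-Ct relative quantification for qRT-PCR
    validation, cumulative fruit abscission rate summaries, and a synthetic
    data generator so the whole pipeline can be exercised and benchmarked
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
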