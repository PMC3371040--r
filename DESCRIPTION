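Package: varfilt
Title: Post-Hoc Filtering and Diagnostics for Called Sequence Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the post-calling stage of a short-read variant
    detection pipeline. Evaluates candidate SNV and indel call sets against
    an experimentally validated truth table (confusion counts, recall,
    precision-style accuracy, F score, validation rate), performs an
    exhaustive grid search over quality (QUAL) and read-depth (DP) cutoffs
    to pick filtering thresholds, screens variants for allele/strand
    imbalance using the DP4 high-quality read counts with a two-sided
    Fisher's exact test, and detects spurious exons (loci accumulating
    artifactual calls from mismapped reads) from per-exon read density and
    mapping-quality statistics with cross-sample recurrence ranking.
    Includes seeded generators for synthetic VCF, SAM and truth-table
    fixtures and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
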