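Package: isomirpair
Title: IsomiR Classification, Quantification and 5'IsomiR Pair Analysis for Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline from small-RNA sequencing reads to 5'isomiR biology:
    adapter trimming, exact-match placement of reads on miRNA precursors,
    5'/3' offset classification in the d5|d3 notation, collapsing of 3'
    variants into canonical versus 5'isomiR groups, reads-per-million
    quantification, detection of highly expressed miRNA/5'isomiR pairs,
    shifted-seed 3'UTR target-site scanning with enrichment testing, and
    patient-cohort statistics (isoform correlation, group comparisons,
    quartile-based Kaplan-Meier survival).  Includes a fully deterministic
    synthetic-data generator with recorded ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    survival,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
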