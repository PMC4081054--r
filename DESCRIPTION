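Package: nbcnv
Title: Rare Copy Number Variant Detection from Exome Read Depth with a
    Negative Binomial Hidden Markov Model
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects rare copy number variants (CNVs) from whole-exome
    read-depth data. Read counts at capture targets are modelled with a
    negative binomial distribution whose per-target mean and variance are
    estimated from reference samples weighted by non-negative least
    squares, with a smoothed variance floor fitted on mean depth and GC
    content. A three-state hidden Markov model with distance-attenuated
    transitions segments targets into deletion, diploid and duplication
    states; calls receive Phred-scaled interval qualities (SQ/NQ) and
    integer copy-number estimates. Includes trio transmission and de novo
    analysis, a batch-structure diagnostic, utilities for counting reads
    over targets from BAM files, and a synthetic cohort simulator for
    offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pracma,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
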