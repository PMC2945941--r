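Package: ctxbias
Title: Context-Dependent Nucleotide Substitution Bias from
    Ancestor-Descendant Alignments
Version: 0.1.0
Authors@R:
    person("Ctxbias", "Developers", email = "ctxbias@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies context-dependent nucleotide
    substitution biases in pairwise ancestor-descendant alignments at
    pattern sizes beyond the adjacent base (2-5 bp and above).  Substitution
    patterns, possibly gapped with N at interior positions, are counted over
    sliding windows; the relative abundance of each pattern is the observed
    conversion proportion divided by the expectation assembled from all of
    its subpatterns, computed either by the recursive definition or by an
    equivalent fast algorithm over full-length gapped subpatterns.
    Per-pattern context bias and per-scale total context bias summarise the
    impact of each context effect on genome composition.  Significance
    machinery includes block-bootstrap confidence intervals, empirical
    p-values against no-bias controls, Benjamini-Hochberg FDR, and a
    bootstrap t-test for comparing total context bias between datasets.
    Simulators generate ancestors, no-bias control descendants,
    context-biased descendants with known ground truth, and
    sequencing-error perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
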