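Package: homfail
Title: Null Model of Homology Detection Failure for Lineage-Specific Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a lineage-specific gene can be explained by
    homology detection failure rather than evolutionary novelty. Fits a
    two-parameter exponential decay of similarity (bit) scores against
    evolutionary distance per gene, extrapolates the predicted score
    distribution to outgroup distances, and computes the probability that
    a homolog evolving at a constant rate would still be detected at a
    chosen E-value threshold. Includes reciprocal-best-hit orthology
    calling from tabular similarity searches, pairwise protein distance
    estimation from concatenated marker alignments, and score- and
    sequence-level simulators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
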