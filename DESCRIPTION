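Package: cedarquant
Title: Strain-Level Metagenomic Abundance Estimation with EM and
    Mass-Preserving Set-Cover Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies strain-level abundances in shotgun metagenomic
    samples. Read alignments are collapsed into range-factorized
    equivalence classes and abundances are estimated by an
    expectation-maximization algorithm whose likelihood is defined over
    those classes, interleaved with an iterative, mass-preserving
    thresholding step that resolves multi-mapping islands (groups of
    highly similar references whose reads are fully ambiguous) by a
    greedy set-cover over critical equivalence classes. Includes a
    simplified selective-alignment mapper (k-mer seeding, maximal exact
    match chaining, affine-gap alignment of inter-seed regions, and a
    fraction-of-best score filter), aggregation of estimates to
    arbitrary NCBI taxonomy ranks, a synthetic community and paired-end
    read simulator, and evaluation metrics (mean squared log error with
    its filtering variants, false-positive counts across read
    thresholds, and rank-table concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
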