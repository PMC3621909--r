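Package: blastospp
Title: Spatial Point Pattern Analysis of Transcriptional States in
    Blastoderm Nuclear Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the spatial arrangement of
    transcriptional states across the nuclear monolayer of the early
    Drosophila blastoderm. Nuclei are treated as points in a bounded
    two-dimensional field and classified by the number of actively
    transcribing gene copies (0, 1 or 2) detected as nascent-transcript
    (intron dot) signals. The package provides first-order summaries
    (densities, nearest-neighbour distances, the Clark-Evans regularity
    index), univariate and bivariate Ripley K and H functions with a
    periodic 3x3 tiling edge correction, Monte Carlo label-permutation
    envelopes with rank-based confidence bounds, Kolmogorov-Smirnov
    detection of radius ranges of significant departure, Voronoi
    immediate-neighbour composition tests, and a nuclear-lineage
    simulator (nested 8/4/2 clones across cycles 11-14) that asks
    whether mitotic inheritance of transcriptional states reproduces
    the dispersed clustering seen in embryos. A synthetic-field
    generator produces blastoderm-like regularly spaced monolayers so
    the whole pipeline runs without microscopy data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deldir,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
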