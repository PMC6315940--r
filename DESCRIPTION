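Package: rnabound
Title: Boundary Detection for Self-Contained Structured RNA Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the boundaries of self-contained structured RNA domains
    inside longer sequence windows from base-pairing probability matrices, as
    produced by single-sequence partition-function folding (RNAfold dot plots)
    or consensus folding of multiple sequence alignments (PETfold-style
    matrices). Implements a segment fitness combining the geometric means of
    in-segment pairing scores, of non-crossing scores for segment positions,
    and of non-spanning scores over flanking margins, maximised exhaustively
    over all candidate segments, together with the weighted inside-minus-
    crossing comparator fitness of Dotu and colleagues. Includes alignment
    quality filters and mean pairwise identity profiling, a signed left/right
    boundary-difference evaluation framework with Wilcoxon rank-sum
    comparison, non-overlapping sub-optimal segment extraction, and a
    synthetic-data module with an exact Boltzmann-ensemble toy folder for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
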