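Package: sigchar
Title: Signature Character Detection for Taxon Diagnoses in Nucleotide Alignments
Version: 0.1.0
Authors@R:
    person("sigchar", "developers", email = "sigchar@example.org", role = c("aut", "cre"))
Description: Detects and classifies diagnostic molecular (signature) characters
    that discriminate a query group of taxa from a reference group in a multiple
    nucleotide sequence alignment. Each alignment column is summarised as a pair
    of character state count vectors over the ordered states A, C, G, T, gap and
    N; columns are ranked by discriminative power (normalized L1 distance),
    query rank and reference rank, and candidate characters are classified as
    binary, asymmetric, noisy or conserved. Pairs of noisy candidate characters
    within a k-window are combined into 36-dimensional pair state vectors and
    re-classified, recovering jointly diagnostic combinations. Also provides a
    per-column Shannon entropy profile of the alignment, group selection from a
    phylogenetic tree or comma-separated taxon lists, seeded fixture generators
    with planted column classes, a command-line interface and TSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
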