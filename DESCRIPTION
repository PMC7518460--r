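Package: nmfinder
Title: Prediction of Nucleomorph-Encoded Genes from Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which transcripts of a transcriptome assembly are
    expressed from a nucleomorph (relic endosymbiont nucleus) rather than the
    host nuclear genome. Transcripts with green-algal homology are selected
    from protein BLAST hit tables, splice variants are collapsed on an
    all-vs-all nucleotide similarity graph, and three features per transcript
    (G+C content at the first and third codon positions of the longest open
    reading frame, and the natural logarithm of TPM expression) are classified
    by a two-component Gaussian mixture model with tied covariance, fitted by
    expectation-maximisation. Transcripts assigned to the low-G+C component
    with posterior probability above 0.95 are called nucleomorph candidates.
    Includes a truth-labelled synthetic-data generator for benchmarking and
    per-category annotation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
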