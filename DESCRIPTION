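Package: PSGscan
Title: Genome Scans for Lineage-Exclusive Positive Selection with
    Dual-Foreground Branch-Site Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects protein-coding genes that evolved under positive
    selection exclusively on one lineage of a phylogeny. Implements the
    branch-site codon substitution model (model A) and its null, a
    pruning-based likelihood over the 61 sense codons with
    maximum-likelihood fitting, the branch-site likelihood-ratio test,
    and empirical Bayes identification of selected codon sites. A scan
    pipeline applies the test twice per orthologous group (foreground
    and counter-foreground lineages), pools all tests into one
    Benjamini-Hochberg false-discovery-rate family, enforces a
    cross-validation exclusivity rule, and filters candidate sites by
    alignment quality and serine coding. A simulator generates codon
    alignments and ortholog-group sets with known ground truth, plus
    matched tissue-expression tables for the cross-reference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
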