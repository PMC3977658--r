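Package: snpfoldscan
Title: Predicting the Effect of Point Mutations on Local RNA Secondary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a single-nucleotide variant disrupts the local
    secondary structure of an RNA. Ensemble base-pair probabilities are
    computed for the wild-type and mutant alleles with a McCaskill-style
    partition function (global or sliding-window local folding), the sequence
    interval of maximal structural divergence is located by a dynamic-
    programming scan using Euclidean distance or Pearson correlation, and the
    observed divergence is converted to an empirical P-value against
    pre-computed null distributions of random substitution effects stratified
    by sequence length and GC content. Three operation modes cover short
    sequences, long sequences, and brute-force screens of every possible
    substitution. Results can be exported as TSV tables, BED6 genome-browser
    tracks, and dot-plot records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
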