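Package: kmerTopics
Title: Whole-Genome k-mer Topic Modeling for Alignment-Free Genome
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Treats whole genomes as documents and their overlapping
    k-mers as words, fits latent Dirichlet allocation by collapsed Gibbs
    sampling, and hierarchically clusters the resulting document-topic
    distributions to compare genomes without alignment.  Includes
    cumulative relative entropy selection of the k-mer length, a
    Jensen-Shannon feature-frequency-profile baseline, and seeded
    synthetic-data generators (bag-of-words corpora from the LDA
    generative process and low-order Markov genomes) so every stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    Biostrings,
    ape,
    mclust,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
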