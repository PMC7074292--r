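#' @importClassesFrom Matrix dgCMatrix
NULL

## Characters allowed in a normalized sequence: uppercase IUPAC nucleotide
## codes plus '-', the record separator inserted between concatenated
## replicons so no k-mer window spans a record boundary.
.SEQ_ALPHABET_RE <- "^[ACGTUMRWSYKVHDBN-]*$"
.RECORD_SEP <- "-"

#' GenomeDocument: one genome treated as a document
#'
#' Holds a single genome's normalized nucleotide sequence together with
#' its identifiers.  Multi-record genomes (chromosome plus plasmids,
#' draft contigs) are stored as one string with a `-` separator between
#' records; `lengthBp` counts nucleotides only, separators excluded.
#'
#' @slot docId short unique identifier used as the document label.
#' @slot accession sequence database accession (e.g. `"AE001273.1"`).
#' @slot organism organism name.
#' @slot family taxonomic family label (may be `""` when unknown).
#' @slot sequence uppercase sequence over the IUPAC alphabet plus `-`.
#' @slot lengthBp numeric count of nucleotide characters (separators
#'   excluded).
#'
#' @seealso [makeDocument()], [readGenomes()], [extractKmers()]
#' @exportClass GenomeDocument
setClass("GenomeDocument",
  representation(docId = "character", accession = "character",
                 organism = "character", family = "character",
                 sequence = "character", lengthBp = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@docId) != 1L || !nzchar(object@docId))
      msg <- c(msg, "docId must be a single non-empty string")
    if (length(object@sequence) != 1L)
      msg <- c(msg, "sequence must be a single string")
    else {
      if (!grepl(.SEQ_ALPHABET_RE, object@sequence))
        msg <- c(msg, "sequence contains characters outside the uppercase IUPAC alphabet")
      nt <- nchar(object@sequence) -
        lengths(regmatches(object@sequence, gregexpr("-", object@sequence, fixed = TRUE)))
      if (nchar(object@sequence) > 0L && object@lengthBp != nt)
        msg <- c(msg, "lengthBp must equal the number of nucleotide characters")
    }
    if (is.null(msg)) TRUE else msg
  })

#' KmerTable: the k-mer multiset of one genome
#'
#' Per-genome counts of overlapping k-mers for a single word length k.
#' For a clean single-record genome of length l the number of valid
#' windows is l - k + 1; windows containing ambiguity codes or record
#' separators are excluded.
#'
#' @slot docId the document the counts belong to.
#' @slot k word length.
#' @slot counts named integer vector, k-mer -> occurrence count, names in
#'   lexicographic order.
#' @slot nValidWindows numeric; total count over all k-mers.
#'
#' @seealso [extractKmers()], [buildCorpus()]
#' @exportClass KmerTable
setClass("KmerTable",
  representation(docId = "character", k = "integer",
                 counts = "integer", nValidWindows = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@k) != 1L || object@k < 1L)
      msg <- c(msg, "k must be a single positive integer")
    if (length(object@counts) > 0L) {
      if (is.null(names(object@counts)))
        msg <- c(msg, "counts must be named by k-mer")
      else {
        if (any(nchar(names(object@counts)) != object@k))
          msg <- c(msg, "all k-mer names must have length k")
        if (any(!grepl("^[ACGT]+$", names(object@counts))))
          msg <- c(msg, "k-mer names must be over {A,C,G,T}")
      }
      if (any(object@counts <= 0L))
        msg <- c(msg, "counts must be positive")
    }
    if (sum(as.numeric(object@counts)) != object@nValidWindows)
      msg <- c(msg, "sum of counts must equal nValidWindows")
    if (is.null(msg)) TRUE else msg
  })

#' KmerCorpus: the filtered documents-by-words count matrix
#'
#' The corpus over M genomes: a sparse M x V matrix of k-mer occurrence
#' counts restricted to the vocabulary of words whose document frequency
#' (number of genomes containing the word at least once) reaches
#' `minDf`.
#'
#' @slot docIds ordered document identifiers (rows).
#' @slot vocabulary ordered, lexicographically sorted k-mer strings
#'   (columns).
#' @slot k word length.
#' @slot counts `dgCMatrix` of occurrence counts.
#' @slot docFreq integer vector of document frequencies of the retained
#'   vocabulary.
#' @slot minDf the document-frequency threshold used.
#'
#' @seealso [buildCorpus()], [corpusStats()], [fitLda()]
#' @exportClass KmerCorpus
setClass("KmerCorpus",
  representation(docIds = "character", vocabulary = "character",
                 k = "integer", counts = "dgCMatrix",
                 docFreq = "integer", minDf = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@counts) != length(object@docIds))
      msg <- c(msg, "counts must have one row per document")
    if (ncol(object@counts) != length(object@vocabulary))
      msg <- c(msg, "counts must have one column per vocabulary word")
    if (length(object@docFreq) != length(object@vocabulary))
      msg <- c(msg, "docFreq must be parallel to vocabulary")
    if (anyDuplicated(object@docIds))
      msg <- c(msg, "docIds must be unique")
    if (anyDuplicated(object@vocabulary))
      msg <- c(msg, "vocabulary must be unique")
    if (is.unsorted(object@vocabulary, strictly = TRUE) && length(object@vocabulary) > 1L)
      msg <- c(msg, "vocabulary must be sorted lexicographically")
    if (length(object@docFreq) && any(object@docFreq < object@minDf))
      msg <- c(msg, "all document frequencies must be >= minDf")
    if (length(object@docFreq)) {
      df <- Matrix::colSums(object@counts > 0)
      if (!all(df == object@docFreq))
        msg <- c(msg, "docFreq must equal the column-wise presence count")
    }
    if (is.null(msg)) TRUE else msg
  })

#' CREProfile: per-genome cumulative relative entropy profile
#'
#' Relative entropies RE_j (bits) of observed j-mer frequencies against
#' the second-order Markov expectation built from (j-1)- and (j-2)-mer
#' frequencies, and their cumulative tail sums
#' CRE(k) = sum_{j=k}^{kMax} RE_j.
#'
#' @slot docId the genome profiled.
#' @slot kMin,kMax inclusive word-length range (kMin >= 3).
#' @slot re named numeric, RE_j per j (names are j as character).
#' @slot cre named numeric, CRE(k) per k.
#'
#' @seealso [creProfile()], [selectK()]
#' @exportClass CREProfile
setClass("CREProfile",
  representation(docId = "character", kMin = "integer", kMax = "integer",
                 re = "numeric", cre = "numeric"),
  validity = function(object) {
    msg <- NULL
    ks <- as.character(seq(object@kMin, object@kMax))
    if (!identical(names(object@re), ks) || !identical(names(object@cre), ks))
      msg <- c(msg, "re and cre must be named by k over [kMin, kMax]")
    if (any(object@re < -1e-9))
      msg <- c(msg, "relative entropies must be non-negative")
    if (length(object@cre) > 1L && any(diff(object@cre) > 1e-9))
      msg <- c(msg, "CRE must be non-increasing in k")
    if (is.null(msg)) TRUE else msg
  })

#' LdaConfig: hyperparameters of the collapsed Gibbs LDA fit
#'
#' @slot nTopics number of topics T.
#' @slot alpha Dirichlet concentration of the document-topic prior;
#'   default 50/T.
#' @slot beta Dirichlet concentration of the topic-word prior; default
#'   0.1.
#' @slot nIter total Gibbs sweeps; default 2000.
#' @slot burnIn sweeps discarded by the posterior-mean estimate; default
#'   a quarter of `nIter`.
#' @slot seed integer RNG seed.
#'
#' @seealso [ldaConfig()], [fitLda()]
#' @exportClass LdaConfig
setClass("LdaConfig",
  representation(nTopics = "integer", alpha = "numeric", beta = "numeric",
                 nIter = "integer", burnIn = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nTopics < 1L) msg <- c(msg, "nTopics must be >= 1")
    if (object@alpha <= 0 || object@beta <= 0)
      msg <- c(msg, "alpha and beta must be positive")
    if (object@burnIn >= object@nIter)
      msg <- c(msg, "burnIn must be smaller than nIter")
    if (is.null(msg)) TRUE else msg
  })

#' LdaModel: a fitted topic model
#'
#' The state of the collapsed Gibbs chain after the final sweep, with the
#' smoothed posterior-mean point estimates
#' theta\[d,j\] = (n_dj + alpha) / (n_d + T alpha) and
#' phi\[j,v\] = (n_jv + beta) / (n_j + V beta).
#'
#' @slot config the [LdaConfig-class] used.
#' @slot docIds,vocabulary row/column labels inherited from the corpus.
#' @slot theta M x T document-topic matrix, rows sum to 1.
#' @slot phi T x V topic-word matrix, rows sum to 1.
#' @slot assignments integer topic label (1..T) per word token, in the
#'   token-stream order (tokens expanded in vocabulary order within each
#'   document).
#' @slot docTopicCounts,topicWordCounts integer count matrices tabulated
#'   from `assignments`.
#' @slot logLik numeric log-likelihood trace recorded during sampling.
#'
#' @seealso [fitLda()], [wordProbability()], [logLikelihood()]
#' @exportClass LdaModel
setClass("LdaModel",
  representation(config = "LdaConfig", docIds = "character",
                 vocabulary = "character", theta = "matrix", phi = "matrix",
                 assignments = "integer", docTopicCounts = "matrix",
                 topicWordCounts = "matrix", logLik = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(abs(rowSums(object@theta) - 1) > 1e-9))
      msg <- c(msg, "theta rows must sum to 1")
    if (any(abs(rowSums(object@phi) - 1) > 1e-9))
      msg <- c(msg, "phi rows must sum to 1")
    if (ncol(object@theta) != object@config@nTopics)
      msg <- c(msg, "theta must have nTopics columns")
    if (is.null(msg)) TRUE else msg
  })

#' FrequencyProfile: normalized k-mer frequencies of one genome
#'
#' The feature-frequency profile of a document over a shared vocabulary:
#' occurrence counts of the vocabulary words normalized to sum to 1
#' within the document (words absent from the document get 0).
#'
#' @slot docId the genome profiled.
#' @slot freq named numeric vector over the shared vocabulary, summing
#'   to 1.
#'
#' @seealso [frequencyProfile()], [jsd()], [ffpTree()]
#' @exportClass FrequencyProfile
setClass("FrequencyProfile",
  representation(docId = "character", freq = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (is.null(names(object@freq)))
      msg <- c(msg, "freq must be named by vocabulary word")
    if (abs(sum(object@freq) - 1) > 1e-9)
      msg <- c(msg, "freq must sum to 1")
    if (any(object@freq < 0)) msg <- c(msg, "freq must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' PlantedTopicModel: ground truth for synthetic corpora
#'
#' A fully specified topic model used to simulate data: T topic-word
#' distributions, one document-topic distribution per family, and a
#' Poisson mean document length xi.
#'
#' @slot phiTrue T x V matrix of topic-word distributions; column names
#'   are the vocabulary.
#' @slot thetaTrue families x T matrix of document-topic distributions;
#'   row names are the family labels.
#' @slot xi positive Poisson mean of the document length N.
#' @slot seed integer RNG seed used by the generators.
#'
#' @seealso [plantedTopicModel()], [generateCorpus()],
#'   [generateFamilyGenomes()]
#' @exportClass PlantedTopicModel
setClass("PlantedTopicModel",
  representation(phiTrue = "matrix", thetaTrue = "matrix",
                 xi = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (is.null(colnames(object@phiTrue)))
      msg <- c(msg, "phiTrue must have the vocabulary as column names")
    if (is.null(rownames(object@thetaTrue)))
      msg <- c(msg, "thetaTrue must have family labels as row names")
    if (ncol(object@thetaTrue) != nrow(object@phiTrue))
      msg <- c(msg, "thetaTrue columns must match phiTrue rows (topics)")
    if (any(abs(rowSums(object@phiTrue) - 1) > 1e-9))
      msg <- c(msg, "phiTrue rows must sum to 1")
    if (any(abs(rowSums(object@thetaTrue) - 1) > 1e-9))
      msg <- c(msg, "thetaTrue rows must sum to 1")
    if (object@xi <= 0) msg <- c(msg, "xi must be positive")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "GenomeDocument", function(object) {
  cat("GenomeDocument", object@docId,
      if (nzchar(object@accession)) paste0("(", object@accession, ")") else "",
      "\n  organism:", object@organism,
      "\n  family:  ", object@family,
      "\n  length:  ", format(object@lengthBp, big.mark = ","), "bp\n")
})

setMethod("show", "KmerTable", function(object) {
  cat("KmerTable for", object@docId, "- k =", object@k, "\n ",
      length(object@counts), "distinct k-mers over",
      format(object@nValidWindows, big.mark = ","), "valid windows\n")
})

setMethod("show", "KmerCorpus", function(object) {
  cat("KmerCorpus:", length(object@docIds), "documents x",
      length(object@vocabulary), "k-mers (k =", object@k,
      ", min document frequency =", object@minDf, ")\n ",
      format(sum(object@counts), big.mark = ","), "tokens\n")
})

setMethod("show", "CREProfile", function(object) {
  cat("CREProfile for", object@docId, "- k in [", object@kMin, ",",
      object@kMax, "]\n")
  print(round(rbind(RE = object@re, CRE = object@cre), 4))
})

setMethod("show", "LdaModel", function(object) {
  cat("LdaModel:", object@config@nTopics, "topics,",
      length(object@docIds), "documents,", length(object@vocabulary),
      "words\n  alpha =", object@config@alpha, ", beta =",
      object@config@beta, ",", object@config@nIter, "Gibbs sweeps, seed",
      object@config@seed, "\n")
})

setMethod("show", "FrequencyProfile", function(object) {
  cat("FrequencyProfile for", object@docId, "over",
      length(object@freq), "words\n")
})

setMethod("show", "PlantedTopicModel", function(object) {
  cat("PlantedTopicModel:", nrow(object@phiTrue), "topics,",
      ncol(object@phiTrue), "words,", nrow(object@thetaTrue),
      "families, xi =", object@xi, "\n")
})
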