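#' Specify a planted topic model
#'
#' Packages the ground truth for the synthetic generators: topic-word
#' distributions, one document-topic distribution per family, and the
#' Poisson mean document length xi.
#'
#' @param phiTrue T x V matrix, rows summing to 1, vocabulary as column
#'   names.
#' @param thetaTrue families x T matrix, rows summing to 1, family
#'   labels as row names.
#' @param xi positive Poisson mean of the document length.
#' @param seed integer RNG seed used by the generators.
#' @return a [PlantedTopicModel-class].
#' @export
plantedTopicModel <- function(phiTrue, thetaTrue, xi, seed = 1) {
  methods::new("PlantedTopicModel", phiTrue = phiTrue, thetaTrue = thetaTrue,
               xi = as.numeric(xi), seed = as.integer(seed))
}

#' Draw distinct sparse topics for simulations
#'
#' Convenience constructor of a [PlantedTopicModel-class] whose T
#' topic-word rows are independent symmetric Dirichlet(`concentration`)
#' draws (sparse, hence well separated for small concentration) and
#' whose per-family theta puts `mainWeight` on the family's own topic
#' and spreads the rest evenly -- one family per topic, mirroring a
#' study design of T families tied to T topics.
#'
#' @param nTopics number of topics (= families).
#' @param vocab character vector of vocabulary words.
#' @param xi Poisson mean document length.
#' @param concentration symmetric Dirichlet parameter of the topic-word
#'   rows; default 0.1.
#' @param mainWeight theta weight of the family's own topic; default
#'   0.8.
#' @param seed integer RNG seed.
#' @return a [PlantedTopicModel-class].
#' @export
randomPlantedModel <- function(nTopics, vocab, xi, concentration = 0.1,
                               mainWeight = 0.8, seed = 1) {
  V <- length(vocab)
  phi <- .withSeed(seed, function() {
    g <- matrix(stats::rgamma(nTopics * V, shape = concentration), nTopics, V)
    g / rowSums(g)
  })
  colnames(phi) <- vocab
  theta <- matrix((1 - mainWeight) / (nTopics - 1), nTopics, nTopics)
  diag(theta) <- mainWeight
  rownames(theta) <- paste0("family", seq_len(nTopics))
  plantedTopicModel(phi, theta, xi, seed = seed)
}

#' Generate a bag-of-words corpus from the LDA generative process
#'
#' For each document: draw the length `N ~ Poisson(xi)`, then for each
#' of the N tokens draw a topic `z ~ Multinomial(theta_family)` and a
#' word `w ~ phi[z, ]`.  Documents inherit their family's theta row
#' (the planted truth fixes theta per family rather than redrawing it
#' per document, so recovery can be scored against a known target).
#'
#' @param planted a [PlantedTopicModel-class].
#' @param familySizes named integer vector, family label -> number of
#'   documents; names must match `rownames(thetaTrue)`.
#' @return list with elements `corpus` (a [KmerCorpus-class] built with
#'   `minDf = 1`), `families` (named character vector per document) and
#'   `thetaTrue` (M x T matrix of the planted document-topic rows).
#' @export
generateCorpus <- function(planted, familySizes) {
  stopifnot(is(planted, "PlantedTopicModel"))
  fams <- names(familySizes)
  if (is.null(fams) || !all(fams %in% rownames(planted@thetaTrue)))
    stop("familySizes must be named by families of the planted model")
  phi <- planted@phiTrue
  V <- ncol(phi)
  T_ <- nrow(phi)
  famPerDoc <- rep(fams, times = familySizes)
  M <- length(famPerDoc)
  ids <- sprintf("%s_doc%02d", famPerDoc, unlist(lapply(familySizes, seq_len)))
  counts <- .withSeed(planted@seed, function() {
    out <- matrix(0, M, V)
    for (d in seq_len(M)) {
      N <- stats::rpois(1L, planted@xi)
      if (N == 0L) next
      zCounts <- stats::rmultinom(1L, N, planted@thetaTrue[famPerDoc[d], ])
      for (j in seq_len(T_)) if (zCounts[j] > 0)
        out[d, ] <- out[d, ] + stats::rmultinom(1L, zCounts[j], phi[j, ])
    }
    out
  })
  dimnames(counts) <- list(ids, colnames(phi))
  ord <- order(colnames(phi))
  counts <- counts[, ord, drop = FALSE]
  # vocabulary = observed words (a word no document drew has no document
  # frequency and is not part of the realized corpus)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  corpus <- methods::new("KmerCorpus", docIds = ids,
                         vocabulary = colnames(counts),
                         k = nchar(colnames(counts)[1L]),
                         counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
                         docFreq = as.integer(colSums(counts > 0)),
                         minDf = 1L)
  list(corpus = corpus,
       families = stats::setNames(famPerDoc, ids),
       thetaTrue = planted@thetaTrue[famPerDoc, , drop = FALSE])
}

#' Generate a genome from a low-order Markov chain
#'
#' Samples a nucleotide sequence from an order-`m` Markov chain over
#' `{A, C, G, T}`.  `trans` is a `4^m` x 4 row-stochastic matrix whose
#' rows are indexed by the length-m context in lexicographic order
#' (AA.., AC.., ...); for `m = 0` a single row (or a length-4 vector)
#' of base probabilities.  The first m bases are drawn i.i.d. from
#' `init` (uniform by default).
#'
#' @param order chain order m >= 0.
#' @param trans transition probabilities (see above).
#' @param length sequence length in bp.
#' @param seed integer RNG seed.
#' @param init length-4 distribution of the initial bases.
#' @param docId,family labels for the returned document.
#' @return a [GenomeDocument-class].
#' @export
generateMarkovGenome <- function(order, trans, length, seed = 1,
                                 init = rep(0.25, 4), docId = "markov",
                                 family = "") {
  order <- as.integer(order)
  if (is.vector(trans)) trans <- matrix(trans, nrow = 1L)
  trans <- as.matrix(trans)
  if (nrow(trans) != 4^order || ncol(trans) != 4L)
    stop("trans must be a 4^order x 4 matrix")
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8))
    stop("trans rows must be non-negative and sum to 1")
  if (abs(sum(init) - 1) > 1e-8) stop("init must sum to 1")
  seq <- .withSeed(seed, function() {
    markovChainCpp(order, trans, init, as.numeric(length))
  })
  makeDocument(stats::setNames(seq, docId), docId = docId, family = family)
}

#' Generate family-structured genomes from planted topics
#'
#' End-to-end DNA fixture: each genome is built by repeatedly drawing a
#' topic from its family's mixture and a k-mer word from that topic,
#' concatenating the words, and truncating to the requested length.
#' Re-extracting k-mers from such a genome recovers the planted words
#' plus junction k-mers spanning word boundaries (a quantifiable noise
#' floor: planted-word windows are 1/k of all windows by construction),
#' which the downstream pipeline must tolerate anyway.
#'
#' @param planted a [PlantedTopicModel-class] whose vocabulary consists
#'   of equal-length k-mer words over `{A, C, G, T}`.
#' @param familySizes named integer vector, family -> number of
#'   genomes.
#' @param length genome length in bp (scalar, or one value per genome);
#'   must be at least k.
#' @return named list of [GenomeDocument-class] objects with family
#'   labels set.
#' @export
generateFamilyGenomes <- function(planted, familySizes, length = 20000) {
  stopifnot(is(planted, "PlantedTopicModel"))
  vocab <- vocabulary(planted)
  k <- unique(nchar(vocab))
  if (length(k) != 1L) stop("vocabulary words must share one length")
  fams <- rep(names(familySizes), times = familySizes)
  M <- length(fams)
  lens <- rep_len(length, M)
  if (any(lens < k)) stop("genome length must be at least k")
  ids <- sprintf("%s_g%02d", fams, unlist(lapply(familySizes, seq_len)))
  T_ <- nrow(planted@phiTrue)
  docs <- .withSeed(planted@seed, function() {
    lapply(seq_len(M), function(d) {
      nWords <- ceiling(lens[d] / k)
      z <- sample.int(T_, nWords, replace = TRUE,
                      prob = planted@thetaTrue[fams[d], ])
      words <- character(nWords)
      for (j in seq_len(T_)) {
        idx <- which(z == j)
        if (length(idx))
          words[idx] <- sample(vocab, length(idx), replace = TRUE,
                               prob = planted@phiTrue[j, ])
      }
      seq <- substr(paste(words, collapse = ""), 1L, lens[d])
      makeDocument(stats::setNames(seq, ids[d]), docId = ids[d],
                   family = fams[d])
    })
  })
  stats::setNames(docs, ids)
}

#' Write synthetic genomes as FASTA plus manifest
#'
#' Writes one FASTA file per genome and a tab-separated manifest
#' (`accession`, `family`, `organism`, `path`) so synthetic fixtures
#' flow through [readGenomes()] and [runPipeline()] exactly like real
#' data.
#'
#' @param docs named list of [GenomeDocument-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeGenomeFixture <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(docs, function(d) {
    p <- file.path(dir, paste0(docIds(d), ".fasta"))
    writeDocumentsFasta(list(d), p)
    basename(p)
  }, character(1))
  man <- data.frame(accession = vapply(docs, docIds, character(1)),
                    family = vapply(docs, genomeFamily, character(1)),
                    organism = vapply(docs, function(d) d@organism, character(1)),
                    path = paths)
  manPath <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manPath)
}
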