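# Shared fixture builders used across test files.

randomSequence <- function(l) {
  paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
}

toyDocument <- function(seq, id = "toy", family = "") {
  makeDocument(stats::setNames(seq, id), docId = id, family = family)
}

# KmerTable built directly from a named count vector (bypasses
# extraction; for corpus-level unit tests)
toyTable <- function(id, counts, k = nchar(names(counts)[1])) {
  counts <- counts[order(names(counts))]
  methods::new("KmerTable", docId = id, k = as.integer(k),
               counts = as.integer(counts) |> stats::setNames(names(counts)),
               nValidWindows = as.numeric(sum(counts)))
}

# the three-document toy corpus used by the corpus-statistics examples
toyCorpusTables <- function() {
  list(toyTable("d1", c(AA = 2L, AC = 1L)),
       toyTable("d2", c(AA = 1L, CC = 3L)),
       toyTable("d3", c(CC = 1L, AC = 1L)))
}

# small abstract bag-of-words corpus (ids w1..wV) for LDA tests
toyLdaCorpus <- function(countsMatrix, ids = rownames(countsMatrix)) {
  vocab <- colnames(countsMatrix)
  stopifnot(!is.unsorted(vocab))
  methods::new("KmerCorpus", docIds = ids, vocabulary = vocab,
               k = nchar(vocab[1]),
               counts = methods::as(methods::as(Matrix::Matrix(countsMatrix, sparse = TRUE),
                                                "generalMatrix"), "CsparseMatrix"),
               docFreq = as.integer(Matrix::colSums(countsMatrix > 0)),
               minDf = 1L)
}

# planted 3-topic model at the study scale: V = 1000, xi = 5000,
# three families with 0.8 of the mass on their own topic
studyPlantedModel <- function(seed, nTopics = 3, V = 1000, xi = 5000) {
  randomPlantedModel(nTopics, sprintf("w%04d", seq_len(V)), xi = xi,
                     concentration = 0.1, mainWeight = 0.8, seed = seed)
}

# mean per-document total-variation distance after topic alignment
thetaRecoveryTV <- function(model, thetaTrue) {
  # the truth's phi may live on a larger vocabulary than the realized
  # corpus, so align topics on the theta columns directly (best
  # permutation = the label matching)
  est <- docTopics(model)
  T_ <- ncol(est)
  perms <- kmerTopics:::.permutations(T_)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    tv <- mean(0.5 * rowSums(abs(est[, perms[r, ], drop = FALSE] - thetaTrue)))
    if (tv < best) best <- tv
  }
  best
}
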