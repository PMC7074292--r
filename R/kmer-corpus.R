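#' Extract overlapping k-mers from a genome
#'
#' Slides a window of width `k` with step 1 over the sequence (forward
#' strand only; no reverse-complement canonicalization).  Windows
#' containing any character outside `{A,C,G,T}` -- IUPAC ambiguity codes
#' or the `-` record separator -- are skipped, so on a clean
#' single-record genome of length l the total count is l - k + 1.
#'
#' @param doc a [GenomeDocument-class], or a plain sequence string.
#' @param k word length (positive integer, at most the nucleotide
#'   length).
#' @return a [KmerTable-class].
#' @examples
#' tab <- extractKmers(makeDocument(c(x = "ACGTA"), docId = "toy"), 3)
#' kmerCounts(tab)
#' @export
extractKmers <- function(doc, k) {
  if (is.character(doc)) doc <- makeDocument(c(seq1 = doc), docId = "seq1")
  stopifnot(is(doc, "GenomeDocument"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k <= 0L)
    stop("k must be a single positive integer")
  if (k > lengthBp(doc))
    stop("k (", k, ") exceeds the genome length (", lengthBp(doc), " bp)")
  res <- countKmersCpp(genomeSequence(doc), k)
  methods::new("KmerTable", docId = docIds(doc), k = k,
               counts = res$counts, nValidWindows = res$n_valid_windows)
}

#' Build the filtered document-term matrix
#'
#' Pools the per-genome k-mer tables into a sparse documents-by-words
#' count matrix and keeps only the words whose document frequency
#' (number of genomes containing the word) is at least `minDf` -- with
#' 30 genomes in three families of ten, the threshold 10 keeps the words
#' shared by at least one family's worth of genomes.
#'
#' @param tables list of [KmerTable-class] objects sharing the same k.
#' @param minDf document-frequency threshold; an integer in
#'   `[1, length(tables)]`, or a fraction in (0, 1) interpreted as a
#'   proportion of documents (rounded up).
#' @return a [KmerCorpus-class].
#' @examples
#' docs <- list(makeDocument(c(x = "AACAA"), docId = "d1"),
#'              makeDocument(c(x = "CCACC"), docId = "d2"))
#' tabs <- lapply(docs, extractKmers, k = 2)
#' buildCorpus(tabs, minDf = 1)
#' @export
buildCorpus <- function(tables, minDf = 10) {
  if (length(tables) == 0L) stop("no k-mer tables supplied")
  ks <- vapply(tables, kmerLength, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all tables must share the same k (got ", paste(unique(ks), collapse = ", "), ")")
  M <- length(tables)
  if (minDf > 0 && minDf < 1) minDf <- ceiling(minDf * M)
  minDf <- as.integer(minDf)
  if (minDf < 1L || minDf > M)
    stop("minDf must lie in [1, ", M, "]")
  ids <- unname(vapply(tables, docIds, character(1)))
  if (anyDuplicated(ids)) stop("duplicate document ids in tables")

  vocab_all <- sort(unique(unlist(lapply(tables, function(t) names(kmerCounts(t))),
                                  use.names = FALSE)))
  df_all <- integer(length(vocab_all))
  names(df_all) <- vocab_all
  for (t in tables) {
    w <- names(kmerCounts(t))
    df_all[w] <- df_all[w] + 1L
  }
  keep <- vocab_all[df_all >= minDf]
  ii <- jj <- xx <- vector("list", M)
  for (d in seq_len(M)) {
    cnt <- kmerCounts(tables[[d]])
    hit <- names(cnt) %in% keep
    cnt <- cnt[hit]
    ii[[d]] <- rep.int(d, length(cnt))
    jj[[d]] <- match(names(cnt), keep)
    xx[[d]] <- as.numeric(cnt)
  }
  counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                                 dims = c(M, length(keep)),
                                 dimnames = list(ids, keep))
  methods::new("KmerCorpus", docIds = ids, vocabulary = keep,
               k = ks[1L], counts = methods::as(counts, "CsparseMatrix"),
               docFreq = unname(df_all[keep]), minDf = minDf)
}

#' Corpus summary statistics
#'
#' The headline numbers of a corpus build: the number of distinct k-mers
#' observed in at least one genome before filtering (`unionDistinct`),
#' the retained vocabulary size (`selectedVocab`), the total number of
#' (genome, word) presence pairs over the retained vocabulary
#' (`presenceSum`, the sum of document frequencies), and the total token
#' count of the matrix (`tokenSum`).
#'
#' @param tables the [KmerTable-class] list the corpus was built from.
#' @param corpus the [KmerCorpus-class].
#' @return named list with elements `unionDistinct`, `selectedVocab`,
#'   `presenceSum`, `tokenSum`.
#' @export
corpusStats <- function(tables, corpus) {
  stopifnot(is(corpus, "KmerCorpus"))
  union_distinct <- length(unique(unlist(lapply(tables, function(t) names(kmerCounts(t))),
                                         use.names = FALSE)))
  list(unionDistinct = union_distinct,
       selectedVocab = length(vocabulary(corpus)),
       presenceSum = sum(as.numeric(corpus@docFreq)),
       tokenSum = sum(corpus@counts))
}

#' Serialize a k-mer table to TSV
#'
#' Two-column tab-separated output (`kmer`, `count`) in vocabulary
#' order.
#'
#' @param table a [KmerTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKmerTable <- function(table, path) {
  utils::write.table(data.frame(kmer = names(kmerCounts(table)),
                                count = as.integer(kmerCounts(table))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / load a corpus
#'
#' Writes the count matrix in MatrixMarket format plus plain-text
#' sidecars: `<prefix>.mtx`, `<prefix>.vocab.txt` (one word per line),
#' `<prefix>.docs.txt` (one document id per line) and `<prefix>.meta.tsv`
#' (k and minDf).  `readCorpus()` reverses the operation.
#'
#' @param corpus a [KmerCorpus-class].
#' @param prefix path prefix for the output files.
#' @return `writeCorpus()` returns `prefix` invisibly; `readCorpus()`
#'   returns the reconstructed [KmerCorpus-class].
#' @export
writeCorpus <- function(corpus, prefix) {
  Matrix::writeMM(corpus@counts, paste0(prefix, ".mtx"))
  writeLines(vocabulary(corpus), paste0(prefix, ".vocab.txt"))
  writeLines(docIds(corpus), paste0(prefix, ".docs.txt"))
  utils::write.table(data.frame(k = corpus@k, minDf = corpus@minDf),
                     paste0(prefix, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(prefix) {
  counts <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  vocab <- readLines(paste0(prefix, ".vocab.txt"))
  ids <- readLines(paste0(prefix, ".docs.txt"))
  meta <- utils::read.table(paste0(prefix, ".meta.tsv"), header = TRUE, sep = "\t")
  dimnames(counts) <- list(ids, vocab)
  methods::new("KmerCorpus", docIds = ids, vocabulary = vocab,
               k = as.integer(meta$k), counts = counts,
               docFreq = as.integer(Matrix::colSums(counts > 0)),
               minDf = as.integer(meta$minDf))
}
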