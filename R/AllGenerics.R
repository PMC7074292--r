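#' Accessors for kmerTopics objects
#'
#' Small accessor generics so slots never need to be reached into
#' directly: `docIds()` returns document identifiers, `vocabulary()` the
#' ordered word list, `kmerCounts()` the count container, `docFreq()`
#' document frequencies, `kmerLength()` the word length k,
#' `docTopics()` the document-topic matrix theta, `topicWords()` the
#' topic-word matrix phi, and `genomeFamily()` the family label(s).
#'
#' @param x a kmerTopics object.
#' @return the corresponding component; matrices carry dimnames.
#' @name accessors
#' @aliases docIds vocabulary kmerCounts docFreq kmerLength docTopics
#'   topicWords genomeFamily
#' @examples
#' doc <- makeDocument(c(rec = "ACGTACGT"), accession = "X1",
#'                     family = "Fam")
#' genomeFamily(doc)
#' kmerCounts(extractKmers(doc, 2))
NULL

#' @rdname accessors
#' @export
setGeneric("docIds", function(x) standardGeneric("docIds"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname accessors
#' @export
setGeneric("docFreq", function(x) standardGeneric("docFreq"))
#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setGeneric("docTopics", function(x) standardGeneric("docTopics"))
#' @rdname accessors
#' @export
setGeneric("topicWords", function(x) standardGeneric("topicWords"))
#' @rdname accessors
#' @export
setGeneric("genomeFamily", function(x) standardGeneric("genomeFamily"))

#' @rdname accessors
setMethod("docIds", "GenomeDocument", function(x) x@docId)
#' @rdname accessors
setMethod("docIds", "KmerTable", function(x) x@docId)
#' @rdname accessors
setMethod("docIds", "KmerCorpus", function(x) x@docIds)
#' @rdname accessors
setMethod("docIds", "LdaModel", function(x) x@docIds)

#' @rdname accessors
setMethod("vocabulary", "KmerCorpus", function(x) x@vocabulary)
#' @rdname accessors
setMethod("vocabulary", "LdaModel", function(x) x@vocabulary)
#' @rdname accessors
setMethod("vocabulary", "PlantedTopicModel", function(x) colnames(x@phiTrue))

#' @rdname accessors
setMethod("kmerCounts", "KmerTable", function(x) x@counts)
#' @rdname accessors
setMethod("kmerCounts", "KmerCorpus", function(x) x@counts)

#' @rdname accessors
setMethod("docFreq", "KmerCorpus", function(x) {
  stats::setNames(x@docFreq, x@vocabulary)
})

#' @rdname accessors
setMethod("kmerLength", "KmerTable", function(x) x@k)
#' @rdname accessors
setMethod("kmerLength", "KmerCorpus", function(x) x@k)

#' @rdname accessors
setMethod("docTopics", "LdaModel", function(x) x@theta)
#' @rdname accessors
setMethod("topicWords", "LdaModel", function(x) x@phi)

#' @rdname accessors
setMethod("genomeFamily", "GenomeDocument", function(x) x@family)
#' @rdname accessors
setMethod("genomeFamily", "list", function(x) {
  vapply(x, genomeFamily, character(1))
})

#' Sequence length in nucleotides
#'
#' Number of nucleotide characters of a [GenomeDocument-class] (record
#' separators excluded).
#'
#' @param x a `GenomeDocument`.
#' @return numeric length in bp.
#' @export
setGeneric("lengthBp", function(x) standardGeneric("lengthBp"))
#' @rdname lengthBp
setMethod("lengthBp", "GenomeDocument", function(x) x@lengthBp)

#' Genome sequence accessor
#'
#' The normalized sequence string of a [GenomeDocument-class], including
#' any `-` record separators.
#'
#' @param x a `GenomeDocument`.
#' @return a single character string.
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname genomeSequence
setMethod("genomeSequence", "GenomeDocument", function(x) x@sequence)
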