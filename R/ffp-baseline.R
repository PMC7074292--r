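#' Feature frequency profile of one genome
#'
#' Normalized frequencies of a shared vocabulary's words within one
#' document: counts of the vocabulary words divided by their total in
#' the document; words absent from the document get 0; words of the
#' document outside the vocabulary are ignored (the total is taken over
#' vocabulary words only).  No over- or under-represented words are
#' removed.
#'
#' @param table a [KmerTable-class].
#' @param vocab ordered character vector of vocabulary words.
#' @return a [FrequencyProfile-class].
#' @export
frequencyProfile <- function(table, vocab) {
  stopifnot(is(table, "KmerTable"))
  if (length(vocab) == 0L) stop("vocabulary must be non-empty")
  cnt <- kmerCounts(table)
  f <- stats::setNames(numeric(length(vocab)), vocab)
  hit <- intersect(names(cnt), vocab)
  if (length(hit) == 0L)
    stop("document ", docIds(table), " shares no words with the vocabulary")
  f[hit] <- cnt[hit]
  methods::new("FrequencyProfile", docId = docIds(table), freq = f / sum(f))
}

#' Jensen--Shannon divergence in bits
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2` and
#' log base 2; symmetric and bounded in `[0, 1]` bits (1 exactly for
#' distributions with disjoint support).
#'
#' @param p,q probability vectors over the same support (or
#'   [FrequencyProfile-class] objects sharing a vocabulary).
#' @return divergence in bits.
#' @examples
#' jsd(c(1, 0), c(0.5, 0.5))
#' @export
jsd <- function(p, q) {
  if (is(p, "FrequencyProfile")) p <- p@freq
  if (is(q, "FrequencyProfile")) q <- q@freq
  if (length(p) != length(q)) stop("profiles must share a vocabulary")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Feature-frequency-profile tree (Sims--Kim style baseline)
#'
#' Pairwise Jensen--Shannon divergences between the profiles, clustered
#' with [hierarchicalCluster()] -- the classical alignment-free baseline
#' the topic tree is compared against, with over-represented words
#' deliberately retained.
#'
#' @param profiles list of [FrequencyProfile-class] objects over the
#'   same vocabulary (>= 2).
#' @param linkage linkage passed to [hierarchicalCluster()].
#' @return an [stats::hclust] tree over the profile doc ids.
#' @export
ffpTree <- function(profiles, linkage = "average") {
  if (length(profiles) < 2L) stop("need at least two profiles")
  ids <- vapply(profiles, function(p) p@docId, character(1))
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    d[i, j] <- d[j, i] <- jsd(profiles[[i]], profiles[[j]])
  hierarchicalCluster(stats::as.dist(d), linkage = linkage)
}
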