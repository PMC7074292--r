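#' Second-order Markov expected k-mer frequencies
#'
#' Extrapolates the expected frequency of each k-mer from the genome's
#' own (k-1)- and (k-2)-mer frequencies: for w = n1..nk,
#' `expected(w) = f(n1..n_{k-1}) * f(n2..nk) / f(n2..n_{k-1})`.
#' Words whose required sub-words were not observed get expected
#' frequency 0 (and are excluded from the divergence downstream).
#'
#' @param freqKm1 named numeric vector of normalized (k-1)-mer
#'   frequencies.
#' @param freqKm2 named numeric vector of normalized (k-2)-mer
#'   frequencies.
#' @param kmers character vector of observed k-mers (k >= 3).
#' @return named numeric vector of expected frequencies, parallel to
#'   `kmers`.
#' @examples
#' markovExpected(c(AC = 0.5, CG = 0.5), c(C = 1), "ACG")
#' @export
markovExpected <- function(freqKm1, freqKm2, kmers) {
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("all k-mers must share one length")
  if (k < 3L) stop("the second-order estimate needs k >= 3")
  pre <- freqKm1[substr(kmers, 1L, k - 1L)]
  suf <- freqKm1[substr(kmers, 2L, k)]
  mid <- freqKm2[substr(kmers, 2L, k - 1L)]
  e <- as.numeric(pre) * as.numeric(suf) / as.numeric(mid)
  e[!is.finite(e)] <- 0
  stats::setNames(e, kmers)
}

#' Relative entropy (Kullback-Leibler divergence) in bits
#'
#' `sum(observed * log2(observed / expected))` over the words with both
#' `observed > 0` and `expected > 0`.  No renormalization is applied
#' here; callers that need a guaranteed non-negative value (see
#' [creProfile()]) restrict both distributions to the common support and
#' renormalize first.
#'
#' @param observed named numeric vector of observed frequencies
#'   (normalized).
#' @param expected named numeric vector of expected frequencies.
#' @return divergence in bits.
#' @examples
#' relativeEntropy(c(a = 0.5, b = 0.5), c(a = 0.25, b = 0.75))
#' @export
relativeEntropy <- function(observed, expected) {
  common <- intersect(names(observed)[observed > 0],
                      names(expected)[expected > 0])
  if (length(common) == 0L)
    stop("observed and expected share no support")
  o <- observed[common]
  e <- expected[common]
  sum(o * log2(o / e))
}

.normalizeCounts <- function(counts) {
  counts / sum(as.numeric(counts))
}

#' Cumulative relative entropy profile of one genome
#'
#' For each word length j in `[kMin, kMax]`, computes the information
#' gain RE_j of the observed j-mer frequencies over the second-order
#' Markov expectation built from the genome's own (j-1)- and (j-2)-mer
#' frequencies ([markovExpected()]); both distributions are restricted
#' to their common support and renormalized there, which makes RE_j a
#' proper KL divergence (hence non-negative).  The cumulative profile is
#' the tail sum `CRE(k) = sum_{j=k}^{kMax} RE_j`, so CRE is
#' non-increasing in k and `CRE(kMax) = RE_kMax`.
#'
#' As CRE approaches zero, longer words stop adding information beyond
#' what shorter words predict -- the basis for choosing k with
#' [selectK()].  Note the plug-in estimate of RE_j is biased upward by
#' roughly `4^j / (2 N ln 2)` bits for a genome of N windows, so kMax
#' should stay well below `log4(N)`.
#'
#' @param doc a [GenomeDocument-class].
#' @param kMin,kMax inclusive word-length range; `kMin >= 3`, and the
#'   genome must be at least `kMax` bp long.
#' @return a [CREProfile-class].
#' @export
creProfile <- function(doc, kMin = 3, kMax = 16) {
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (kMin < 3L) stop("kMin must be >= 3 (second-order estimate)")
  if (kMax < kMin) stop("kMax must be >= kMin")
  if (lengthBp(doc) < kMax)
    stop("genome ", docIds(doc), " is shorter than kMax = ", kMax)
  freqs <- lapply(seq(kMin - 2L, kMax), function(j) {
    .normalizeCounts(kmerCounts(extractKmers(doc, j)))
  })
  names(freqs) <- as.character(seq(kMin - 2L, kMax))
  re <- vapply(seq(kMin, kMax), function(j) {
    obs <- freqs[[as.character(j)]]
    exp_f <- markovExpected(freqs[[as.character(j - 1L)]],
                            freqs[[as.character(j - 2L)]],
                            names(obs))
    common <- names(obs)[obs > 0 & exp_f[names(obs)] > 0]
    o <- obs[common] / sum(obs[common])
    e <- exp_f[common] / sum(exp_f[common])
    max(relativeEntropy(o, e), 0)  # clamp -0 from rounding
  }, numeric(1))
  names(re) <- as.character(seq(kMin, kMax))
  cre <- rev(cumsum(rev(re)))
  methods::new("CREProfile", docId = docIds(doc), kMin = kMin, kMax = kMax,
               re = re, cre = cre)
}

#' Select the word length k from CRE profiles
#'
#' Returns the smallest k in the shared range for which every genome's
#' CRE(k) falls below the threshold (default 0.1 bits) -- the first word
#' length at which no genome gains appreciable information from longer
#' words.
#'
#' @param profiles list of [CREProfile-class] objects sharing a k range.
#' @param threshold CRE threshold in bits; default 0.1.
#' @return the selected integer k.
#' @export
selectK <- function(profiles, threshold = 0.1) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  kmins <- vapply(profiles, function(p) p@kMin, integer(1))
  kmaxs <- vapply(profiles, function(p) p@kMax, integer(1))
  if (length(unique(kmins)) != 1L || length(unique(kmaxs)) != 1L)
    stop("all profiles must share the same k range")
  for (k in seq(kmins[1L], kmaxs[1L])) {
    vals <- vapply(profiles, function(p) p@cre[[as.character(k)]], numeric(1))
    if (all(vals < threshold)) return(k)
  }
  stop("no k in [", kmins[1L], ", ", kmaxs[1L], "] brings every genome's ",
       "CRE below ", threshold, " bits; raise kMax and recompute the profiles")
}

#' Write CRE profiles as a tidy TSV
#'
#' One row per (genome, word length): columns `doc_id`, `j`, `re`,
#' `cre`, suitable for external box-plotting.
#'
#' @param profiles list of [CREProfile-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCreProfiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(doc_id = p@docId, j = as.integer(names(p@re)),
               re = unname(p@re), cre = unname(p@cre))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
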