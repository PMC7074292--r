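# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# substring-enumeration k-mer counter
naiveKmerCounts <- function(seq, k) {
  n <- nchar(seq)
  if (k > n) return(integer(0))
  wins <- substring(seq, 1:(n - k + 1), k:n)
  wins <- wins[!grepl("[^ACGT]", wins)]
  tab <- table(wins)
  stats::setNames(as.integer(tab), names(tab))
}

# exact collapsed LDA posterior over all T^n topic assignments
# doc/word: 0-based token ids as fed to the sampler
enumerateCollapsedPosterior <- function(doc, word, M, V, T_, alpha, beta) {
  n <- length(doc)
  nStates <- T_^n
  logp <- numeric(nStates)
  for (s in seq_len(nStates) - 1L) {
    z <- integer(n)
    code <- s
    for (i in seq_len(n)) {
      z[i] <- code %% T_
      code <- code %/% T_
    }
    ndj <- matrix(0L, M, T_)
    njv <- matrix(0L, T_, V)
    for (i in seq_len(n)) {
      ndj[doc[i] + 1L, z[i] + 1L] <- ndj[doc[i] + 1L, z[i] + 1L] + 1L
      njv[z[i] + 1L, word[i] + 1L] <- njv[z[i] + 1L, word[i] + 1L] + 1L
    }
    lp <- 0
    for (d in seq_len(M))
      lp <- lp + sum(lgamma(ndj[d, ] + alpha)) - lgamma(sum(ndj[d, ]) + T_ * alpha)
    for (j in seq_len(T_))
      lp <- lp + sum(lgamma(njv[j, ] + beta)) - lgamma(sum(njv[j, ]) + V * beta)
    logp[s + 1L] <- lp
  }
  p <- exp(logp - max(logp))
  p / sum(p)
}

# by-hand UPGMA (average linkage) on a distance matrix: returns merge
# heights in order
naiveUpgmaHeights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (j > i) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestD) { bestD <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestD)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
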