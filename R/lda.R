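#' Construct an LDA configuration
#'
#' Conventional collapsed-Gibbs defaults: `alpha = 50/nTopics`,
#' `beta = 0.1`, 2000 sweeps.  All are overridable.
#'
#' @param nTopics number of topics T.
#' @param alpha document-topic Dirichlet concentration (> 0).
#' @param beta topic-word Dirichlet concentration (> 0).
#' @param nIter total Gibbs sweeps.
#' @param burnIn sweeps discarded when `estimate = "mean"` in
#'   [fitLda()]; must be `< nIter`.  Defaults to a quarter of `nIter`.
#' @param seed integer RNG seed (the fit is bit-reproducible given the
#'   same corpus, config and seed).
#' @return an [LdaConfig-class].
#' @examples
#' ldaConfig(3, seed = 42)
#' @export
ldaConfig <- function(nTopics, alpha = 50 / nTopics, beta = 0.1,
                      nIter = 2000, burnIn = nIter %/% 4, seed = 1) {
  methods::new("LdaConfig", nTopics = as.integer(nTopics),
               alpha = as.numeric(alpha), beta = as.numeric(beta),
               nIter = as.integer(nIter), burnIn = as.integer(burnIn),
               seed = as.integer(seed))
}

## Expand the count matrix into a token stream: tokens appear in
## vocabulary order within each document (the model is exchangeable, so
## the layout does not affect the posterior).  0-based ids for C++.
.tokenStream <- function(corpus) {
  m <- corpus@counts
  M <- nrow(m)
  doc <- vector("list", M)
  word <- vector("list", M)
  for (d in seq_len(M)) {
    row <- m[d, ]
    nz <- which(row > 0)
    doc[[d]] <- rep.int(d - 1L, sum(row[nz]))
    word[[d]] <- rep.int(as.integer(nz - 1L), as.integer(row[nz]))
  }
  list(doc = unlist(doc), word = unlist(word))
}

## Run `fun` under a locally seeded RNG, restoring the caller's stream.
.withSeed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

.smoothTheta <- function(ndj, alpha) {
  th <- (ndj + alpha) / (rowSums(ndj) + ncol(ndj) * alpha)
  th
}

.smoothPhi <- function(njv, beta) {
  (njv + beta) / (rowSums(njv) + ncol(njv) * beta)
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Each token's topic is initialized uniformly at random and then
#' resampled for `nIter` sweeps from the collapsed full conditional
#' `P(z = j) \propto (n_dj + alpha) (n_jv + beta) / (n_j + V beta)`.
#' The returned point estimates are the smoothed posterior means at the
#' final state, `theta[d,j] = (n_dj + alpha) / (n_d + T alpha)` and
#' `phi[j,v] = (n_jv + beta) / (n_j + V beta)`.  With
#' `estimate = "mean"`, theta and phi are instead averaged over
#' post-burn-in samples (every `thin` sweeps), each sample aligned to
#' the final state's topics with [matchTopics()] before averaging.
#'
#' Topics are identifiable only up to permutation (label switching);
#' compare fits after [matchTopics()].
#'
#' @param corpus a [KmerCorpus-class] (every document must contain at
#'   least one token).
#' @param config an [LdaConfig-class].
#' @param estimate `"final"` (default) or `"mean"`.
#' @param thin sweep interval between averaged samples when
#'   `estimate = "mean"`.
#' @param traceEvery record the token log-likelihood every this many
#'   sweeps (0 disables).
#' @return an [LdaModel-class].
#' @export
fitLda <- function(corpus, config, estimate = c("final", "mean"),
                   thin = 10, traceEvery = 10) {
  stopifnot(is(corpus, "KmerCorpus"), is(config, "LdaConfig"))
  estimate <- match.arg(estimate)
  nd <- Matrix::rowSums(corpus@counts)
  if (any(nd == 0))
    stop("document(s) with zero tokens: ",
         paste(corpus@docIds[nd == 0], collapse = ", "))
  stream <- .tokenStream(corpus)
  n <- length(stream$doc)
  M <- length(corpus@docIds)
  V <- length(corpus@vocabulary)
  T_ <- config@nTopics
  if (T_ > n)
    warning("more topics (", T_, ") than tokens (", n, ")")

  fit <- .withSeed(config@seed, function() {
    if (estimate == "final") {
      res <- ldaGibbsCpp(stream$doc, stream$word, M, V, T_,
                         config@alpha, config@beta, config@nIter,
                         traceEvery, FALSE)
      res$theta <- .smoothTheta(res$ndj, config@alpha)
      res$phi <- .smoothPhi(res$njv, config@beta)
      res
    } else {
      res <- ldaGibbsCpp(stream$doc, stream$word, M, V, T_,
                         config@alpha, config@beta, config@burnIn,
                         traceEvery, FALSE)
      trace <- res$trace
      nSamples <- (config@nIter - config@burnIn) %/% thin
      thetaSamples <- vector("list", nSamples)
      phiSamples <- vector("list", nSamples)
      for (s in seq_len(nSamples)) {
        res <- ldaGibbsCpp(stream$doc, stream$word, M, V, T_,
                           config@alpha, config@beta, thin,
                           traceEvery, FALSE, zInit = res$z)
        trace <- c(trace, res$trace)
        thetaSamples[[s]] <- .smoothTheta(res$ndj, config@alpha)
        phiSamples[[s]] <- .smoothPhi(res$njv, config@beta)
      }
      phiRef <- phiSamples[[nSamples]]
      theta <- matrix(0, M, T_); phi <- matrix(0, T_, V)
      for (s in seq_len(nSamples)) {
        perm <- matchTopics(phiRef, phiSamples[[s]])
        theta <- theta + thetaSamples[[s]][, perm, drop = FALSE]
        phi <- phi + phiSamples[[s]][perm, , drop = FALSE]
      }
      res$theta <- theta / nSamples
      res$phi <- phi / nSamples
      res$trace <- trace
      res
    }
  })

  dimnames(fit$theta) <- list(corpus@docIds, paste0("topic", seq_len(T_)))
  dimnames(fit$phi) <- list(paste0("topic", seq_len(T_)), corpus@vocabulary)
  dimnames(fit$ndj) <- dimnames(fit$theta)
  dimnames(fit$njv) <- dimnames(fit$phi)
  methods::new("LdaModel", config = config, docIds = corpus@docIds,
               vocabulary = corpus@vocabulary,
               theta = fit$theta, phi = fit$phi,
               assignments = as.integer(fit$z + 1L),
               docTopicCounts = fit$ndj, topicWordCounts = fit$njv,
               logLik = as.numeric(fit$trace))
}

#' Per-document word probabilities under the mixture
#'
#' The marginal probability of each vocabulary word in document d,
#' `P(w) = sum_j phi[j, w] * theta[d, j]` -- the document's topic
#' mixture applied to the topic-word distributions.
#'
#' @param model a fitted [LdaModel-class].
#' @param d document index (1-based) or document id.
#' @return named numeric vector over the vocabulary, summing to 1.
#' @export
wordProbability <- function(model, d) {
  stopifnot(is(model, "LdaModel"))
  if (is.character(d)) d <- match(d, model@docIds)
  if (is.na(d) || d < 1 || d > nrow(model@theta))
    stop("document index out of range")
  p <- as.numeric(model@theta[d, , drop = FALSE] %*% model@phi)
  stats::setNames(p, model@vocabulary)
}

#' Corpus log-likelihood under the fitted mixture
#'
#' `sum_d sum_tokens log P(w)` with `P(w)` from [wordProbability()],
#' i.e. the token log-likelihood of the corpus under the model's point
#' estimates of theta and phi.
#'
#' @param model a fitted [LdaModel-class].
#' @param corpus the [KmerCorpus-class] to score (same vocabulary).
#' @return a finite numeric scalar.
#' @export
logLikelihood <- function(model, corpus) {
  stopifnot(is(model, "LdaModel"), is(corpus, "KmerCorpus"))
  if (!identical(model@vocabulary, corpus@vocabulary) ||
      !identical(model@docIds, corpus@docIds))
    stop("model and corpus dimensions do not agree")
  pw <- model@theta %*% model@phi  # M x V
  sum(corpus@counts * log(pw))
}

#' Align topics between two fits
#'
#' Mixture likelihoods are invariant to topic permutation, so two fits
#' (or a fit and the ground truth) are comparable only after matching
#' topics.  Finds the permutation `perm` minimizing the total L1
#' distance between `reference` and `phi[perm, ]` by exhaustive search
#' over permutations (intended for the small T regime this method runs
#' in).
#'
#' @param reference T x V topic-word matrix to align to.
#' @param phi T x V topic-word matrix to permute.
#' @return integer permutation such that `phi[perm, ]` matches
#'   `reference` row-by-row.
#' @export
matchTopics <- function(reference, phi) {
  T_ <- nrow(reference)
  stopifnot(nrow(phi) == T_, ncol(phi) == ncol(reference))
  if (T_ > 8L) stop("exhaustive matching supports at most 8 topics")
  cost <- matrix(0, T_, T_)
  for (i in seq_len(T_)) for (j in seq_len(T_))
    cost[i, j] <- sum(abs(reference[i, ] - phi[j, ]))
  perms <- .permutations(T_)
  tot <- vapply(seq_len(nrow(perms)), function(r) {
    sum(cost[cbind(seq_len(T_), perms[r, ])])
  }, numeric(1))
  perms[which.min(tot), ]
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Empirical distribution of Gibbs assignment states
#'
#' Runs the collapsed Gibbs chain on a tiny corpus and tallies the full
#' topic-assignment vector once per sweep.  States are encoded base-T
#' over the token stream (token i contributes `z_i * T^i`), so the code
#' space is `T^n`; only corpora small enough for that to be exact
#' (`T^n < 2^53`) are accepted.  The chain's stationary distribution is
#' the exact collapsed posterior over assignments, which makes this the
#' package's sampler-correctness diagnostic: the tallied frequencies can
#' be compared against brute-force enumeration of the posterior.
#'
#' @param corpus a small [KmerCorpus-class].
#' @param config an [LdaConfig-class]; `nIter` sweeps are tallied after
#'   `burnIn` discarded sweeps.
#' @return data.frame with columns `code` (numeric state code) and
#'   `count` (sweeps observed in that state).
#' @export
sampleStateDistribution <- function(corpus, config) {
  stopifnot(is(corpus, "KmerCorpus"), is(config, "LdaConfig"))
  stream <- .tokenStream(corpus)
  n <- length(stream$doc)
  if (config@nTopics^n >= 2^53)
    stop("corpus too large for exact state tallying")
  res <- .withSeed(config@seed, function() {
    warm <- ldaGibbsCpp(stream$doc, stream$word, length(corpus@docIds),
                        length(corpus@vocabulary), config@nTopics,
                        config@alpha, config@beta, config@burnIn, 0L, FALSE)
    ldaGibbsCpp(stream$doc, stream$word, length(corpus@docIds),
                length(corpus@vocabulary), config@nTopics,
                config@alpha, config@beta, config@nIter, 0L, TRUE,
                zInit = warm$z)
  })
  data.frame(code = res$state_codes, count = res$state_counts)
}

#' Write a fitted model's distributions to TSV + JSON
#'
#' `<prefix>.theta.tsv` (documents x topics), `<prefix>.phi.tsv`
#' (topics x words) and `<prefix>.config.json` holding the
#' hyperparameters, seed and log-likelihood trace.
#'
#' @param model a fitted [LdaModel-class].
#' @param prefix path prefix.
#' @return `prefix`, invisibly.
#' @export
writeLdaModel <- function(model, prefix) {
  utils::write.table(data.frame(doc_id = model@docIds, model@theta,
                                check.names = FALSE),
                     paste0(prefix, ".theta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(topic = rownames(model@phi), model@phi,
                                check.names = FALSE),
                     paste0(prefix, ".phi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- list(nTopics = model@config@nTopics, alpha = model@config@alpha,
              beta = model@config@beta, nIter = model@config@nIter,
              burnIn = model@config@burnIn, seed = model@config@seed,
              logLik = model@logLik)
  jsonlite::write_json(cfg, paste0(prefix, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
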