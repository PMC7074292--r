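test_that("single-topic fits collapse to closed forms", {
  m <- matrix(c(3, 1, 0, 2), 2, 2, dimnames = list(c("d1", "d2"), c("wa", "wb")))
  corpus <- toyLdaCorpus(m)
  fit <- fitLda(corpus, ldaConfig(1, nIter = 20, seed = 1))
  expect_equal(unname(docTopics(fit)[, 1]), c(1, 1))
  beta <- fit@config@beta
  expect_equal(unname(topicWords(fit)[1, ]),
               (c(4, 2) + beta) / (6 + 2 * beta))  # column sums + smoothing
  # with one topic, the mixture collapses to phi
  expect_equal(wordProbability(fit, 1), topicWords(fit)[1, ])
})

test_that("identical corpus, config and seed reproduce the fit exactly", {
  set.seed(10)
  g <- generateCorpus(studyPlantedModel(10, V = 60, xi = 150),
                      c(family1 = 3, family2 = 3, family3 = 3))
  cfg <- ldaConfig(3, nIter = 100, seed = 77)
  f1 <- fitLda(g$corpus, cfg)
  f2 <- fitLda(g$corpus, cfg)
  expect_identical(f1@assignments, f2@assignments)
  expect_identical(docTopics(f1), docTopics(f2))
  expect_identical(topicWords(f1), topicWords(f2))
  # a different seed gives a different chain
  f3 <- fitLda(g$corpus, ldaConfig(3, nIter = 100, seed = 78))
  expect_false(identical(f1@assignments, f3@assignments))
})

test_that("count slots tabulate the assignments and theta/phi are their smoothed means", {
  set.seed(11)
  g <- generateCorpus(studyPlantedModel(11, V = 40, xi = 80),
                      c(family1 = 2, family2 = 2, family3 = 2))
  fit <- fitLda(g$corpus, ldaConfig(3, nIter = 50, seed = 5))
  stream <- kmerTopics:::.tokenStream(g$corpus)
  ndj <- t(sapply(seq_along(docIds(fit)), function(d)
    tabulate(fit@assignments[stream$doc == d - 1L], 3)))
  expect_equal(unname(fit@docTopicCounts), ndj)
  cfg <- fit@config
  expect_equal(unname(docTopics(fit)),
               unname((ndj + cfg@alpha) / (rowSums(ndj) + 3 * cfg@alpha)))
  expect_equal(rowSums(topicWords(fit)), stats::setNames(rep(1, 3), rownames(fit@phi)))
})

test_that("two documents with disjoint vocabularies separate into distinct topics", {
  m <- matrix(c(30, 25, 0, 0,
                0, 0, 28, 27), 2, 4, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("wa", "wb", "wc", "wd")))
  corpus <- toyLdaCorpus(m)
  for (seed in 1:10) {
    fit <- fitLda(corpus, ldaConfig(2, alpha = 0.5, nIter = 500, seed = seed))
    th <- docTopics(fit)
    dom <- apply(th, 1, which.max)
    expect_false(dom[1] == dom[2])
    expect_true(all(apply(th, 1, max) > 0.9))
  }
})

test_that("wordProbability mixes topics and sums to one", {
  set.seed(12)
  g <- generateCorpus(studyPlantedModel(12, V = 30, xi = 60),
                      c(family1 = 2, family2 = 2, family3 = 2))
  fit <- fitLda(g$corpus, ldaConfig(3, nIter = 50, seed = 3))
  p <- wordProbability(fit, 2)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(unname(p),
               as.numeric(docTopics(fit)[2, ] %*% topicWords(fit)))
  # degenerate mixture: theta = (1, 0, 0) picks out phi row 1
  fit@theta[1, ] <- c(1, 0, 0)
  expect_equal(unname(wordProbability(fit, 1)), unname(topicWords(fit)[1, ]))
  expect_error(wordProbability(fit, 99), "out of range")
})

test_that("logLikelihood is invariant to topic relabeling and trends upward early", {
  set.seed(13)
  g <- generateCorpus(studyPlantedModel(13, V = 100, xi = 300),
                      c(family1 = 3, family2 = 3, family3 = 3))
  fit <- fitLda(g$corpus, ldaConfig(3, nIter = 200, seed = 9), traceEvery = 1)
  ll <- logLikelihood(fit, g$corpus)
  expect_true(is.finite(ll))

  perm <- c(2, 3, 1)
  permuted <- fit
  permuted@theta <- fit@theta[, perm]
  permuted@phi <- fit@phi[perm, ]
  expect_equal(logLikelihood(permuted, g$corpus), ll)

  # smoothed trace over 50-sweep windows is non-decreasing during burn-in
  tr <- fit@logLik
  w <- c(mean(tr[1:50]), mean(tr[51:100]), mean(tr[101:150]))
  expect_true(all(diff(w) > 0))
})

test_that("posterior-mean estimate averages aligned samples and stays close to the final state", {
  set.seed(14)
  g <- generateCorpus(studyPlantedModel(14, V = 50, xi = 200),
                      c(family1 = 3, family2 = 3, family3 = 3))
  fin <- fitLda(g$corpus, ldaConfig(3, nIter = 400, seed = 4))
  avg <- fitLda(g$corpus, ldaConfig(3, nIter = 400, burnIn = 200, seed = 4),
                estimate = "mean")
  expect_equal(rowSums(docTopics(avg)), stats::setNames(rep(1, 9), docIds(avg)),
               tolerance = 1e-9)
  perm <- matchTopics(topicWords(fin), topicWords(avg))
  tv <- mean(0.5 * rowSums(abs(docTopics(avg)[, perm] - docTopics(fin))))
  expect_lt(tv, 0.15)
})

test_that("matchTopics undoes a known permutation", {
  set.seed(15)
  phi <- matrix(stats::rgamma(4 * 20, 0.2), 4, 20)
  phi <- phi / rowSums(phi)
  perm <- c(3, 1, 4, 2)
  expect_identical(matchTopics(phi, phi[perm, ]), order(perm))
  expect_identical(matchTopics(phi, phi), 1:4)
})

test_that("documents with zero tokens are rejected", {
  m <- matrix(c(2, 0), 2, 1, dimnames = list(c("d1", "d2"), "wa"))
  expect_error(fitLda(toyLdaCorpus(m), ldaConfig(2, nIter = 10)),
               "zero tokens")
})
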