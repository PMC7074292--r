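test_that("extractKmers slides an overlapping window and skips ambiguous windows", {
  tab <- extractKmers("ACGTA", 3)
  expect_identical(kmerCounts(tab), c(ACG = 1L, CGT = 1L, GTA = 1L))
  expect_identical(tab@nValidWindows, 3)  # l - k + 1 = 5 - 3 + 1

  # windows overlapping an N (or a record separator) are dropped
  expect_identical(kmerCounts(extractKmers("ACNGT", 2)), c(AC = 1L, GT = 1L))
  doc <- makeDocument(c(a = "AAA", b = "CCC"))
  expect_identical(kmerCounts(extractKmers(doc, 2)), c(AA = 2L, CC = 2L))

  expect_error(extractKmers("ACGT", 0), "positive")
  expect_error(extractKmers("ACGT", 5), "exceeds")
})

test_that("extractKmers agrees with a naive substring oracle on random sequences", {
  set.seed(42)
  for (rep in 1:25) {
    l <- sample(20:200, 1)
    k <- sample(1:8, 1)
    seq <- randomSequence(l)
    # inject occasional ambiguity codes
    if (rep %% 3 == 0) {
      pos <- sample(l, 2)
      substr(seq, pos[1], pos[1]) <- "N"
      substr(seq, pos[2], pos[2]) <- "R"
    }
    got <- kmerCounts(extractKmers(seq, k))
    want <- naiveKmerCounts(seq, k)
    expect_identical(got[order(names(got))], want[order(names(want))],
                     info = sprintf("l=%d k=%d", l, k))
  }
})

test_that("buildCorpus filters by document frequency as in the toy example", {
  tabs <- toyCorpusTables()
  corpus <- buildCorpus(tabs, minDf = 2)
  expect_identical(vocabulary(corpus), c("AA", "AC", "CC"))
  expect_identical(docFreq(corpus), c(AA = 2L, AC = 2L, CC = 2L))
  expect_identical(as.numeric(kmerCounts(corpus)["d2", c("AA", "CC")]), c(1, 3))

  # minDf = 1 keeps the union, minDf = M keeps the intersection
  expect_length(vocabulary(buildCorpus(tabs, minDf = 1)), 3L)
  expect_identical(vocabulary(buildCorpus(tabs, minDf = 3)), character(0))
  twoOfThree <- buildCorpus(tabs, minDf = 0.5)  # fraction form: ceil(0.5 * 3)
  expect_identical(vocabulary(twoOfThree), c("AA", "AC", "CC"))

  expect_error(buildCorpus(list()), "no k-mer tables")
  expect_error(buildCorpus(list(toyTable("a", c(AA = 1L)),
                                toyTable("b", c(AAA = 1L)))), "share the same k")
})

test_that("corpusStats reports union, vocabulary, presence and token sums", {
  tabs <- toyCorpusTables()
  stats2 <- corpusStats(tabs, buildCorpus(tabs, minDf = 2))
  expect_identical(stats2$unionDistinct, 3L)
  expect_identical(stats2$selectedVocab, 3L)
  expect_identical(stats2$presenceSum, 6)
  expect_identical(stats2$tokenSum, 9)

  one <- list(toyTable("solo", c(AA = 4L, AC = 1L)))
  stats1 <- corpusStats(one, buildCorpus(one, minDf = 1))
  expect_identical(stats1$unionDistinct, stats1$selectedVocab)
  expect_identical(stats1$presenceSum, as.numeric(stats1$selectedVocab))
})

test_that("corpus invariants: conservation, monotonicity, presence bounds", {
  set.seed(99)
  docs <- lapply(1:6, function(i) toyDocument(randomSequence(300), sprintf("d%d", i)))
  tabs <- lapply(docs, extractKmers, k = 3)

  unfiltered <- buildCorpus(tabs, minDf = 1)
  stats_ <- corpusStats(tabs, unfiltered)
  expect_identical(stats_$tokenSum,
                   sum(vapply(tabs, function(t) t@nValidWindows, numeric(1))))

  sizes <- vapply(1:6, function(df) corpusStats(tabs, buildCorpus(tabs, df))$selectedVocab,
                  integer(1))
  expect_true(all(diff(sizes) <= 0))

  for (df in c(2L, 4L)) {
    st <- corpusStats(tabs, buildCorpus(tabs, df))
    if (st$selectedVocab > 0) {
      ratio <- st$presenceSum / st$selectedVocab
      expect_gte(ratio, df)
      expect_lte(ratio, length(tabs))
    }
  }
})

test_that("corpus round-trips through MatrixMarket serialization", {
  tabs <- toyCorpusTables()
  corpus <- buildCorpus(tabs, minDf = 2)
  prefix <- file.path(withr::local_tempdir(), "toy")
  writeCorpus(corpus, prefix)
  back <- readCorpus(prefix)
  expect_identical(vocabulary(back), vocabulary(corpus))
  expect_identical(docIds(back), docIds(corpus))
  expect_equal(as.matrix(kmerCounts(back)), as.matrix(kmerCounts(corpus)))
  expect_identical(back@minDf, corpus@minDf)
})
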