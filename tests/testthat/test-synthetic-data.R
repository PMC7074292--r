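test_that("generateCorpus follows the planted generative process", {
  # T = 1: empirical word frequencies converge to phi (law of large numbers)
  V <- 50
  phi <- matrix(stats::rgamma(V, 1, 1), 1, V,
                dimnames = list(NULL, sprintf("w%03d", 1:V)))
  phi <- phi / sum(phi)
  theta <- matrix(1, 1, 1, dimnames = list("fam", NULL))
  pm <- plantedTopicModel(phi, theta, xi = 1e5, seed = 51)
  g <- generateCorpus(pm, c(fam = 1))
  emp <- as.numeric(g$corpus@counts) / sum(g$corpus@counts)
  tv <- 0.5 * sum(abs(emp - phi[1, vocabulary(g$corpus)]))
  expect_lt(tv, 0.02)

  # Poisson document lengths: mean over many docs within 3 s.e. of xi
  pm2 <- plantedTopicModel(phi, theta, xi = 5, seed = 52)
  g2 <- generateCorpus(pm2, c(fam = 2000))
  lens <- Matrix::rowSums(g2$corpus@counts)
  expect_lt(abs(mean(lens) - 5), 3 * sqrt(5 / 2000))

  # disjoint-support topics with one-hot theta: tokens stay in-support
  phi3 <- rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  colnames(phi3) <- c("w1", "w2", "w3", "w4")
  th3 <- rbind(A = c(1, 0), B = c(0, 1))
  g3 <- generateCorpus(plantedTopicModel(phi3, th3, xi = 200, seed = 53),
                       c(A = 3, B = 3))
  cnt <- as.matrix(g3$corpus@counts)
  expect_equal(sum(cnt[g3$families == "A", colnames(cnt) %in% c("w3", "w4")]), 0)
  expect_equal(sum(cnt[g3$families == "B", colnames(cnt) %in% c("w1", "w2")]), 0)

  # seeded: identical calls are identical
  g3b <- generateCorpus(plantedTopicModel(phi3, th3, xi = 200, seed = 53),
                        c(A = 3, B = 3))
  expect_identical(as.matrix(g3$corpus@counts), as.matrix(g3b$corpus@counts))
})

test_that("generateMarkovGenome honors composition, transitions and seeds", {
  g0 <- generateMarkovGenome(0, rep(0.25, 4), 1e6, seed = 61)
  comp <- table(strsplit(genomeSequence(g0), "")[[1]]) / lengthBp(g0)
  expect_true(all(abs(comp - 0.25) < 0.005))

  # P(A->A) = 0.9: AA frequency ~ 0.9 * P(A) at stationarity (symmetric
  # chain, so the stationary distribution is uniform)
  tr <- matrix(0.1 / 3, 4, 4); diag(tr) <- 0.9
  g1 <- generateMarkovGenome(1, tr, 1e6, seed = 62)
  aa <- kmerCounts(extractKmers(g1, 2))[["AA"]] / (lengthBp(g1) - 1)
  expect_equal(aa, 0.9 * 0.25, tolerance = 0.02)

  expect_identical(genomeSequence(generateMarkovGenome(1, tr, 500, seed = 7)),
                   genomeSequence(generateMarkovGenome(1, tr, 500, seed = 7)))
  expect_error(generateMarkovGenome(1, matrix(1, 4, 4), 100), "sum to 1")
  expect_error(generateMarkovGenome(2, tr, 100), "4\\^order")
})

test_that("generateFamilyGenomes concatenates planted words into genomes", {
  phi <- matrix(1, 1, 1, dimnames = list(NULL, "AAAA"))
  theta <- matrix(1, 1, 1, dimnames = list("fam", NULL))
  pm <- plantedTopicModel(phi, theta, xi = 10, seed = 1)
  g <- generateFamilyGenomes(pm, c(fam = 1), length = 12)
  expect_identical(genomeSequence(g[[1]]), "AAAAAAAAAAAA")
  expect_identical(genomeFamily(g[[1]]), "fam")

  # two disjoint-word families: k-mer count vectors separate by family
  set.seed(63)
  k <- 6
  mkwords <- function(n) unique(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""), ""))
  w1 <- mkwords(40); w2 <- setdiff(mkwords(40), w1)
  phi2 <- rbind(c(rep(1 / length(w1), length(w1)), rep(0, length(w2))),
                c(rep(0, length(w1)), rep(1 / length(w2), length(w2))))
  colnames(phi2) <- c(w1, w2)
  th2 <- rbind(A = c(1, 0), B = c(0, 1))
  pm2 <- plantedTopicModel(phi2, th2, xi = 10, seed = 64)
  docs <- generateFamilyGenomes(pm2, c(A = 4, B = 4), length = 3000)
  tabs <- lapply(docs, extractKmers, k = k)
  corpus <- buildCorpus(tabs, minDf = 1)
  m <- as.matrix(kmerCounts(corpus))
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  fams <- genomeFamily(docs)
  within <- between <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    cs <- cosine(m[i, ], m[j, ])
    if (fams[i] == fams[j]) within <- c(within, cs) else between <- c(between, cs)
  }
  expect_gt(min(within), max(between))

  expect_error(generateFamilyGenomes(pm, c(fam = 1), length = 2), "at least k")
})

test_that("synthetic fixtures flow through FASTA + manifest I/O unchanged", {
  pm <- studyPlantedModel(65, V = 30, xi = 50)
  # 4-mer DNA vocabulary version for file round-trip
  vocab <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3))[1:30, ],
                 1, paste, collapse = "")
  pmDna <- randomPlantedModel(3, sort(unique(vocab)), xi = 50, seed = 65)
  docs <- generateFamilyGenomes(pmDna, c(family1 = 2, family2 = 2, family3 = 2),
                                length = 200)
  dir <- withr::local_tempdir()
  manPath <- writeGenomeFixture(docs, dir)
  back <- readGenomes(manPath)
  expect_identical(vapply(back, genomeSequence, ""),
                   vapply(docs, genomeSequence, ""))
  expect_identical(unname(genomeFamily(back)),
                   unname(genomeFamily(docs)))
})
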