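test_that("topicDistanceMatrix implements both metrics", {
  theta <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0))
  d <- as.matrix(topicDistanceMatrix(theta))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], sqrt(2))

  theta2 <- rbind(a = c(1, 0), b = c(0, 1))
  dj <- as.matrix(topicDistanceMatrix(theta2, metric = "jensen-shannon"))
  expect_equal(dj["a", "b"], 1)

  expect_error(topicDistanceMatrix(rbind(c(0.5, 0.2))), "sum to 1")
  expect_error(topicDistanceMatrix(theta, metric = "mahalanobis"))
})

test_that("hierarchicalCluster merges the nearest pair first and yields n-1 merges", {
  m <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tree <- hierarchicalCluster(stats::as.dist(m))
  expect_identical(nrow(tree$merge), 2L)
  expect_identical(sort(tree$merge[1, ]), c(-2L, -1L))  # {a,b} first

  bad <- m; bad[1, 2] <- bad[2, 1] <- Inf
  expect_error(hierarchicalCluster(stats::as.dist(bad)), "non-finite")
})

test_that("average linkage reproduces a by-hand UPGMA table", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- 2; m["a", "c"] <- 5; m["b", "c"] <- 3
  m["a", "d"] <- 9; m["b", "d"] <- 7; m["c", "d"] <- 8
  m <- m + t(m)
  d <- stats::as.dist(m)
  tree <- hierarchicalCluster(d, linkage = "average")
  # by hand: {a,b}@2, then {ab,c}@(5+3)/2, then all@(9+7+8)/3
  expect_equal(tree$height, c(2, 4, 8))
  expect_equal(tree$height, naiveUpgmaHeights(d))
  expect_identical(sort(tree$merge[1, ]), c(-2L, -1L))
})

test_that("cutTreeK cuts the highest merges deterministically", {
  m <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tree <- hierarchicalCluster(stats::as.dist(m))
  expect_identical(unname(cutTreeK(tree, 1)), rep(1L, 3))
  expect_identical(length(unique(cutTreeK(tree, 3))), 3L)
  two <- cutTreeK(tree, 2)
  expect_identical(two[["a"]], two[["b"]])
  expect_false(two[["a"]] == two[["c"]])
  expect_error(cutTreeK(tree, 4), "nClusters")

  # k clusters are always k non-empty groups
  set.seed(21)
  theta <- matrix(stats::rgamma(30, 1), 10, 3)
  theta <- theta / rowSums(theta)
  rownames(theta) <- paste0("g", 1:10)
  t2 <- hierarchicalCluster(topicDistanceMatrix(theta))
  for (k in 1:10)
    expect_identical(length(unique(cutTreeK(t2, k))), k)
})

test_that("agreement scores purity, ARI and misplaced genomes", {
  fams <- stats::setNames(rep(c("F1", "F2", "F3"), each = 3), paste0("g", 1:9))
  perfect <- stats::setNames(rep(1:3, each = 3), paste0("g", 1:9))
  a <- agreement(perfect, fams)
  expect_equal(a$purity, 1)
  expect_equal(a$ari, 1)
  expect_length(a$misplaced, 0L)

  # one genome in a foreign majority-cluster
  one_off <- perfect
  one_off[["g1"]] <- 2L
  a2 <- agreement(one_off, fams)
  expect_equal(a2$purity, 8 / 9)
  expect_identical(a2$misplaced, "g1")

  # everything lumped together: purity = largest family share, ARI = 0
  lumped <- stats::setNames(rep(1L, 9), paste0("g", 1:9))
  a3 <- agreement(lumped, fams)
  expect_equal(a3$purity, 1 / 3)
  expect_equal(a3$ari, 0)

  # purity is invariant under cluster relabeling
  relabeled <- stats::setNames(c(7L, 7L, 7L, 5L, 5L, 5L, 9L, 9L, 9L), paste0("g", 1:9))
  expect_equal(agreement(relabeled, fams)$purity, 1)
  expect_error(agreement(perfect, fams[-1]), "same document ids")
})

test_that("Newick export derives branch lengths from merge heights and round-trips", {
  m <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree <- hierarchicalCluster(stats::as.dist(m))
  expect_identical(toNewick(tree), "(a:2,b:2);")

  m3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m3["a", "b"] <- m3["b", "a"] <- 2
  m3["a", "c"] <- m3["c", "a"] <- m3["b", "c"] <- m3["c", "b"] <- 6
  t3 <- hierarchicalCluster(stats::as.dist(m3))
  nwk <- toNewick(t3)
  expect_identical(nwk, "(c:6,(a:2,b:2):4);")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  expect_identical(ape::Ntip(phy), 3L)
})
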