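#' Pairwise distances between document-topic distributions
#'
#' Builds the distance matrix over genomes from the rows of theta,
#' either euclidean (default) or the Jensen--Shannon divergence in bits
#' (see [jsd()]).
#'
#' @param theta M x T matrix of document-topic probabilities with
#'   document ids as row names; rows must sum to 1.
#' @param metric `"euclidean"` or `"jensen-shannon"`.
#' @return a [stats::dist] object labelled by the document ids.
#' @export
topicDistanceMatrix <- function(theta, metric = c("euclidean", "jensen-shannon")) {
  metric <- match.arg(metric)
  if (any(abs(rowSums(theta) - 1) > 1e-6))
    stop("theta rows must sum to 1")
  if (metric == "euclidean") return(stats::dist(theta, method = "euclidean"))
  M <- nrow(theta)
  d <- matrix(0, M, M, dimnames = list(rownames(theta), rownames(theta)))
  for (i in seq_len(M)) for (j in seq_len(M)) if (j > i)
    d[i, j] <- d[j, i] <- jsd(theta[i, ], theta[j, ])
  stats::as.dist(d)
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering of a distance matrix via
#' [stats::hclust()]; `"average"` linkage (UPGMA, the default) yields an
#' ultrametric tree, `"ward"` maps to Ward's D2 criterion.  The merge
#' order is deterministic given the distances.
#'
#' @param d a [stats::dist] object with labels (n >= 2, all finite).
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @return an [stats::hclust] tree with n - 1 merges.
#' @export
hierarchicalCluster <- function(d, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (attr(d, "Size") < 2L) stop("need at least two observations")
  stats::hclust(d, method = switch(linkage, average = "average",
                                   complete = "complete", ward = "ward.D2"))
}

#' Cut a cluster tree into k groups
#'
#' Removes the `nClusters - 1` highest merges; labels are arbitrary but
#' deterministic (leaf-order of first appearance).
#'
#' @param tree an [stats::hclust] tree.
#' @param nClusters number of groups, between 1 and the number of
#'   leaves.
#' @return named integer vector, document id -> cluster label.
#' @export
cutTreeK <- function(tree, nClusters) {
  n <- length(tree$labels)
  if (nClusters < 1L || nClusters > n)
    stop("nClusters must lie in [1, ", n, "]")
  stats::cutree(tree, k = nClusters)
}

#' Agreement between a clustering and the family labels
#'
#' Scores how well a flat clustering reproduces the taxonomic families:
#' purity (fraction of genomes whose cluster's majority family is their
#' own), the adjusted Rand index (chance-corrected, via
#' [mclust::adjustedRandIndex()]), and the list of misplaced genomes --
#' those sitting in a cluster dominated by a foreign family.
#'
#' @param clusters named vector, document id -> cluster label.
#' @param families named vector, document id -> family label (same
#'   ids).
#' @return list with elements `purity`, `ari`, `misplaced`.
#' @export
agreement <- function(clusters, families) {
  ids <- names(clusters)
  if (is.null(ids) || !setequal(ids, names(families)))
    stop("clusters and families must be named by the same document ids")
  families <- families[ids]
  majority <- character(0)
  misplaced <- character(0)
  correct <- 0L
  for (cl in unique(clusters)) {
    members <- ids[clusters == cl]
    tab <- sort(table(families[members]), decreasing = TRUE)
    # ties broken lexicographically among equally frequent families
    top <- names(tab)[tab == tab[1L]]
    maj <- sort(top)[1L]
    hit <- families[members] == maj
    correct <- correct + sum(hit)
    misplaced <- c(misplaced, members[!hit])
  }
  list(purity = correct / length(ids),
       ari = mclust::adjustedRandIndex(as.vector(clusters), as.vector(families)),
       misplaced = sort(misplaced))
}

#' Export a cluster tree as Newick
#'
#' Converts the merge tree to `ape`'s `phylo` representation and writes
#' Newick with branch lengths derived from the merge heights (a node at
#' height h and its child at height g are separated by h - g; leaves sit
#' at height 0, so a two-leaf tree merging at height h is
#' `"(a:h,b:h);"`).
#'
#' @param tree an [stats::hclust] tree.
#' @return a single Newick string (terminated by `;`).
#' @export
toNewick <- function(tree) {
  phy <- ape::as.phylo(tree)
  # as.phylo.hclust halves the heights (ultrametric convention); restore
  # edge lengths on the merge-height scale
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy)
}
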