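#' Run the whole-genome topic-modeling pipeline end to end
#'
#' Orchestrates the full method: read genomes, (optionally) choose the
#' word length k by cumulative relative entropy, decompose genomes into
#' k-mers, build the document-frequency-filtered corpus, fit LDA by
#' collapsed Gibbs sampling, hierarchically cluster the document-topic
#' distributions, score agreement with the manifest's family labels,
#' and (optionally) build the Jensen--Shannon feature-frequency-profile
#' baseline tree on the same vocabulary.  Identical inputs, config and
#' seed reproduce every output exactly.
#'
#' @param manifest manifest path or `data.frame` (see [readManifest()]),
#'   or `NULL` when `documents` is given.
#' @param documents optional list of [GenomeDocument-class] objects
#'   (bypasses file input).
#' @param k `"auto"` to select k by CRE (threshold `creThreshold` over
#'   `kRange`), or a fixed integer.
#' @param kRange inclusive k range scanned when `k = "auto"`.
#' @param creThreshold CRE threshold in bits; default 0.1.
#' @param minDf document-frequency filter; integer, or fraction of
#'   documents.  Default 10, the per-family genome count of the
#'   30-genome design this method was built around.
#' @param nTopics number of topics T (required; choose deliberately,
#'   e.g. the number of families under study).
#' @param alpha,beta,nIter,burnIn LDA hyperparameters, see
#'   [ldaConfig()]; `burnIn` defaults to a quarter of `nIter`.
#' @param metric,linkage distance and linkage for the theta tree, see
#'   [topicDistanceMatrix()] and [hierarchicalCluster()].
#' @param cut number of flat clusters to cut; defaults to `nTopics`.
#' @param ffpBaseline also build the FFP baseline tree; default `TRUE`.
#' @param seed integer seed driving the LDA fit.
#' @param outDir if non-`NULL`, [writeReport()] is called on the result.
#' @param verbose print per-stage progress; default `TRUE`.
#' @return a `RunReport`: a named list with the resolved `config`, the
#'   chosen `k`, `corpusStats`, `creProfiles` (when `k = "auto"`),
#'   `model` ([LdaModel-class]), `tree` and `ffpTree`
#'   ([stats::hclust]), their Newick strings, flat `clusters`, and
#'   `agreement` / `ffpAgreement` when family labels are present.
#' @export
runPipeline <- function(manifest = NULL, documents = NULL, k = "auto",
                        kRange = c(3, 16), creThreshold = 0.1, minDf = 10,
                        nTopics, alpha = 50 / nTopics, beta = 0.1,
                        nIter = 2000, burnIn = nIter %/% 4,
                        metric = "euclidean", linkage = "average",
                        cut = nTopics, ffpBaseline = TRUE, seed = 1,
                        outDir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[kmerTopics] ", ...)
  if (is.null(documents)) {
    if (is.null(manifest)) stop("supply a manifest or a list of documents")
    documents <- readGenomes(manifest)
  }
  say(length(documents), " genome(s) read")
  families <- genomeFamily(documents)
  names(families) <- vapply(documents, docIds, character(1))

  creProfiles <- NULL
  if (identical(k, "auto")) {
    say("computing CRE profiles over k in [", kRange[1], ", ", kRange[2], "]")
    creProfiles <- lapply(documents, creProfile, kMin = kRange[1], kMax = kRange[2])
    k <- selectK(creProfiles, threshold = creThreshold)
    say("selected k = ", k, " (CRE threshold ", creThreshold, " bits)")
  } else {
    k <- as.integer(k)
    say("using fixed k = ", k)
  }

  tables <- lapply(documents, extractKmers, k = k)
  corpus <- buildCorpus(tables, minDf = minDf)
  stats_ <- corpusStats(tables, corpus)
  say("corpus: ", stats_$unionDistinct, " distinct ", k, "-mers, ",
      stats_$selectedVocab, " retained at min document frequency ",
      corpus@minDf, ", presence sum ", stats_$presenceSum,
      ", ", stats_$tokenSum, " tokens")

  config <- ldaConfig(nTopics, alpha = alpha, beta = beta, nIter = nIter,
                      burnIn = burnIn, seed = seed)
  say("fitting LDA: ", nTopics, " topics, ", nIter, " Gibbs sweeps, seed ", seed)
  model <- fitLda(corpus, config)
  say("final token log-likelihood: ",
      format(utils::tail(model@logLik, 1), digits = 8))

  d <- topicDistanceMatrix(docTopics(model), metric = metric)
  tree <- hierarchicalCluster(d, linkage = linkage)
  clusters <- cutTreeK(tree, cut)
  agr <- if (all(nzchar(families))) agreement(clusters, families) else NULL
  if (!is.null(agr))
    say("topic tree at ", cut, " clusters: purity ",
        round(agr$purity, 3), ", ARI ", round(agr$ari, 3))

  ffp <- ffpAgr <- NULL
  if (ffpBaseline) {
    profiles <- lapply(tables, frequencyProfile, vocab = vocabulary(corpus))
    ffp <- ffpTree(profiles, linkage = linkage)
    if (all(nzchar(families))) {
      ffpAgr <- agreement(cutTreeK(ffp, cut), families)
      say("FFP baseline tree: purity ", round(ffpAgr$purity, 3),
          ", ARI ", round(ffpAgr$ari, 3))
    }
  }

  report <- list(
    config = list(k = k, kMode = if (is.null(creProfiles)) "fixed" else "auto",
                  kRange = kRange, creThreshold = creThreshold,
                  minDf = corpus@minDf, nTopics = as.integer(nTopics),
                  alpha = alpha, beta = beta, nIter = as.integer(nIter),
                  burnIn = as.integer(burnIn), metric = metric,
                  linkage = linkage, cut = as.integer(cut), seed = as.integer(seed)),
    nGenomes = length(documents),
    families = families,
    corpusStats = stats_,
    creProfiles = creProfiles,
    corpus = corpus,
    model = model,
    tree = tree,
    newick = toNewick(tree),
    clusters = clusters,
    agreement = agr,
    ffpTree = ffp,
    ffpNewick = if (!is.null(ffp)) toNewick(ffp) else NULL,
    ffpAgreement = ffpAgr)
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (resolved config, corpus statistics, agreement
#' scores, cluster assignments -- stable key order), the theta/phi
#' TSVs, the corpus in MatrixMarket form, CRE profiles (when computed),
#' Newick trees, and a flat `clusters.tsv` (doc_id, cluster, family).
#'
#' @param report a report list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = report$config,
                  nGenomes = report$nGenomes,
                  corpusStats = report$corpusStats,
                  agreement = if (!is.null(report$agreement))
                    list(purity = report$agreement$purity,
                         ari = report$agreement$ari,
                         misplaced = report$agreement$misplaced)
                  else NULL,
                  ffpAgreement = if (!is.null(report$ffpAgreement))
                    list(purity = report$ffpAgreement$purity,
                         ari = report$ffpAgreement$ari,
                         misplaced = report$ffpAgreement$misplaced)
                  else NULL)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(report$model))
    writeLdaModel(report$model, file.path(dir, "lda"))
  if (!is.null(report$corpus))
    writeCorpus(report$corpus, file.path(dir, "corpus"))
  if (!is.null(report$creProfiles))
    writeCreProfiles(report$creProfiles, file.path(dir, "cre_profiles.tsv"))
  if (!is.null(report$newick))
    writeLines(report$newick, file.path(dir, "topic_tree.nwk"))
  if (!is.null(report$ffpNewick))
    writeLines(report$ffpNewick, file.path(dir, "ffp_tree.nwk"))
  if (!is.null(report$clusters)) {
    utils::write.table(
      data.frame(doc_id = names(report$clusters),
                 cluster = as.integer(report$clusters),
                 family = unname(report$families[names(report$clusters)])),
      file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(dir)
}
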