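#' Read a FASTA file into named sequences
#'
#' Reads a (possibly gzipped) multi-record FASTA file with
#' [Biostrings::readDNAStringSet()] and returns the records as a named
#' character vector in file order, sequences uppercased and whitespace
#' stripped.  Record ids are the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a FASTA file (plain or `.gz`).
#' @return named character vector, one element per record; `character(0)`
#'   for an empty file.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt", "ACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(con, n = 1000L, warn = FALSE)
  close(con)
  nonempty <- which(nzchar(trimws(head_lines)))
  if (length(nonempty) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(head_lines[nonempty[1L]]), ">"))
    stop("malformed FASTA in ", path, ": sequence line before any header at line ",
         nonempty[1L])
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- toupper(gsub("[[:space:]]", "", as.character(seqs)))
  names(out) <- sub("[[:space:]].*$", "", names(seqs))
  out
}

#' Build a GenomeDocument from FASTA records
#'
#' Normalizes and joins one genome's records (chromosome plus plasmids,
#' or draft contigs) into a single document.  Records are joined with a
#' single `-` separator -- a character outside `{A,C,G,T}` -- so that no
#' k-mer window later spans a record boundary; `lengthBp` counts
#' nucleotides only.
#'
#' @param records named character vector of sequences as returned by
#'   [readFasta()] (at least one record).
#' @param accession accession string, e.g. `"AE001273.1"`.
#' @param organism organism name.
#' @param family taxonomic family label.
#' @param docId document identifier; defaults to the accession.
#' @return a [GenomeDocument-class].
#' @examples
#' makeDocument(c(a = "AAA", b = "CCC"), accession = "X1")
#' @export
makeDocument <- function(records, accession = "", organism = "",
                         family = "", docId = accession) {
  if (length(records) == 0L) stop("at least one record is required")
  if (!nzchar(docId)) {
    docId <- if (!is.null(names(records)) && nzchar(names(records)[1L]))
      names(records)[1L] else "doc"
  }
  norm <- toupper(gsub("[[:space:]]", "", unname(records)))
  if (sum(nchar(norm)) == 0L)
    stop("empty sequence after normalization for ", docId)
  bad <- !grepl(.SEQ_ALPHABET_RE, norm)
  if (any(bad))
    stop("record ", which(bad)[1L], " contains non-IUPAC characters")
  methods::new("GenomeDocument",
               docId = as.character(docId), accession = as.character(accession),
               organism = as.character(organism), family = as.character(family),
               sequence = paste(norm, collapse = .RECORD_SEP),
               lengthBp = as.numeric(sum(nchar(norm))))
}

#' Read a genome manifest table
#'
#' Reads the delimited manifest mapping each genome to its accession,
#' family, organism and FASTA path.  Tab- or comma-separated is detected
#' from the header line; the columns `accession`, `family`, `organism`
#' and `path` must be present.
#'
#' @param path path to a TSV/CSV file with a header.
#' @return a `data.frame` with character columns.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  man <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  needed <- c("accession", "family", "organism", "path")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(man$accession))
    stop("manifest accessions must be unique")
  if (any(!nzchar(man$family)))
    stop("manifest families must be non-empty")
  man
}

#' Read all genomes listed in a manifest
#'
#' For each manifest row, reads the FASTA file and builds a
#' [GenomeDocument-class] via [makeDocument()].  Relative paths are
#' resolved against the manifest's directory.
#'
#' @param manifest a manifest `data.frame` (see [readManifest()]) or a
#'   path to one.
#' @param baseDir directory against which relative FASTA paths are
#'   resolved; defaults to the manifest's directory when `manifest` is a
#'   path, else the working directory.
#' @return named list of `GenomeDocument`s, in manifest order.
#' @export
readGenomes <- function(manifest, baseDir = NULL) {
  if (is.character(manifest)) {
    if (is.null(baseDir)) baseDir <- dirname(manifest)
    manifest <- readManifest(manifest)
  }
  if (is.null(baseDir)) baseDir <- "."
  docs <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(baseDir, manifest$path[i])
    makeDocument(readFasta(p),
                 accession = manifest$accession[i],
                 organism = manifest$organism[i],
                 family = manifest$family[i])
  })
  names(docs) <- vapply(docs, docIds, character(1))
  docs
}

#' The 30-genome bacterial study manifest
#'
#' The accession / family / organism / genome-size table of the 30
#' complete bacterial genomes (ten each from *Chlamydiales*,
#' *Vibrionaceae* and *Yersiniaceae*) that the whole-genome topic-model
#' study design is built around.  Sequences are not shipped: download
#' each accession from the sequence databases as
#' `<accession>.fasta`, point `dir` at the download directory, and the
#' returned manifest can be handed straight to [readGenomes()] or
#' [runPipeline()].
#'
#' @param dir directory holding the genome FASTA files; prefixed to the
#'   `path` column when given.
#' @return a manifest `data.frame` with columns `accession`, `family`,
#'   `organism`, `genome_size_bp`, `path`.
#' @export
table1Manifest <- function(dir = NULL) {
  man <- utils::read.table(system.file("extdata", "table1_manifest.tsv",
                                       package = "kmerTopics"),
                           header = TRUE, sep = "\t",
                           colClasses = c(rep("character", 3), "numeric",
                                          "character"),
                           quote = "\"", comment.char = "")
  if (!is.null(dir)) man$path <- file.path(dir, man$path)
  man
}

#' Write GenomeDocuments back to FASTA
#'
#' Writes each document as one FASTA record named by its `docId`.  The
#' stored sequence is written verbatim (including `-` separators, which
#' are legal `DNAString` characters), so reading the file back with
#' [readFasta()] reproduces the sequences exactly.
#'
#' @param docs list of [GenomeDocument-class] objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeDocumentsFasta <- function(docs, path) {
  seqs <- Biostrings::DNAStringSet(vapply(docs, genomeSequence, character(1)))
  names(seqs) <- vapply(docs, docIds, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
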