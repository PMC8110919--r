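## Plain-text IO: read files, proteome FASTA, manifests and the TSV caches
## used to persist kmer tables, backgrounds, score matrices and statistics.

#' Load a sample's 12-mer reads from a plain-text file
#'
#' One peptide per line. Lines that are not 12 characters long or contain
#' letters outside the 20 standard amino acids are dropped (with a logged
#' count), and duplicate peptides are collapsed: all downstream counts are
#' over unique 12-mers.
#'
#' @param path path to the read file.
#' @param sampleId sample identifier; defaults to the file name without
#'   extension.
#' @param minReads warn if fewer unique reads survive filtering (production
#'   screens yield ~1e6+ unique 12-mers per sample; desk-scale data are
#'   smaller, so this is a warning, not an error).
#' @return a [PeptideReadSet-class].
#' @export
loadReads <- function(path, sampleId = NULL, minReads = 10000L) {
  if (!file.exists(path)) stop("read file not found: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rs <- PeptideReadSet(sampleId, lines, filter = TRUE)
  if (nReads(rs) == 0L)
    stop("no valid 12-mer reads in ", path)
  if (nReads(rs) < minReads)
    warning(sprintf("sample %s has only %d unique reads (< %d)",
                    sampleId, nReads(rs), minReads))
  rs
}

#' Write a read set to a plain-text file (one peptide per line)
#'
#' @param readSet a [PeptideReadSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReads <- function(readSet, path) {
  writeLines(readSequences(readSet), path)
  invisible(path)
}

#' Load a target proteome from FASTA
#'
#' Reads a (possibly UniProt-style) protein FASTA into a data.frame of
#' protein records. The accession is the first whitespace-delimited token of
#' the header (e.g. `sp|P14678|RSMB_HUMAN`); the remainder is kept as the
#' description. Sequences are uppercased; non-standard letters (X, U, B, Z)
#' are allowed and masked during scoring.
#'
#' @param path FASTA file.
#' @return data.frame with columns `protein_id`, `description`, `sequence`,
#'   `length`, in file order.
#' @export
loadProteome <- function(path) {
  if (!file.exists(path)) stop("proteome FASTA not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty proteome FASTA: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate accessions in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  data.frame(protein_id = ids, description = desc, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a proteome data.frame to FASTA
#'
#' @param proteome data.frame as returned by [loadProteome()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- ifelse(nzchar(proteome$description),
                      paste(proteome$protein_id, proteome$description),
                      proteome$protein_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a sample manifest
#'
#' TSV with header columns `sample_id`, `path`, `cohort`; cohort labels must
#' be `case` or `control`. Relative read-file paths are resolved against the
#' manifest's own directory. At least two controls are required because the
#' background normalization needs a standard deviation.
#'
#' @param path manifest TSV.
#' @param requireControls if `TRUE` (default), error with fewer than 2
#'   controls.
#' @return data.frame with columns `sample_id`, `path`, `cohort`.
#' @export
readManifest <- function(path, requireControls = TRUE) {
  m <- .readTsv(path, c("sample_id", "path", "cohort"))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_ids in manifest: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(m$cohort), c("case", "control"))
  if (length(bad))
    stop("invalid cohort labels in manifest (must be case/control): ",
         paste(bad, collapse = ", "))
  if (requireControls && sum(m$cohort == "control") < 2L)
    stop("manifest must contain at least 2 control samples")
  rel <- !grepl("^(/|~|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(normalizePath(path)), m$path[rel])
  m
}

#' Write a sample manifest
#' @param manifest data.frame with columns `sample_id`, `path`, `cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  .writeTsv(manifest[, c("sample_id", "path", "cohort")], path)
}

## ---- generic TSV helpers ---------------------------------------------------

## Numeric columns serialized at 15 significant digits so that round trips
## are lossless at double precision.
.writeTsv <- function(df, path, meta = NULL) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.15g", df[[col]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), "=", vapply(meta, as.character, "")), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

.readTsv <- function(path, requiredCols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  if (!is.null(requiredCols)) {
    missing <- setdiff(requiredCols, names(df))
    if (length(missing))
      stop(sprintf("%s: missing required columns: %s",
                   path, paste(missing, collapse = ", ")))
  }
  df
}

.readTsvMeta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- sub("^# ", "", lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

## ---- typed table persistence ----------------------------------------------

#' Persist and restore kmer tables, backgrounds, scores and statistics
#'
#' TSV serialization for the pipeline's intermediate artifacts. Floating
#' point values are written with 15 significant digits so write-then-read is
#' lossless; sample-level metadata (sample id, read count, amino-acid
#' frequencies) ride along as `#`-prefixed header lines.
#'
#' Schemas: kmer tables have columns `kmer`, `k`, `n`, `e`, `E`, `F`;
#' backgrounds `kmer`, `k`, `mean`, `sd`, `n_controls`; score matrices (long
#' form) `sample_id`, `protein_id`, `piwas_score`, `piwas_loc`; protein
#' statistics the columns produced by [rankProteome()]. A read with missing
#' columns errors, naming them.
#'
#' @param table,background,scores,stats the object to write.
#' @param path file path.
#' @return writers return `path` invisibly; readers the restored object.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeKmerTable <- function(table, path) {
  stopifnot(is(table, "KmerTable"))
  .writeTsv(kmerEntries(table), path,
            meta = list(sample_id = sampleId(table),
                        read_count = nReads(table),
                        aa_freqs = paste(sprintf("%s:%.15g", names(aaFrequencies(table)),
                                                 aaFrequencies(table)), collapse = ",")))
}

#' @rdname tableIO
#' @export
readKmerTable <- function(path) {
  df <- .readTsv(path, c("kmer", "k", "n", "e", "E", "F"))
  meta <- .readTsvMeta(path)
  if (is.null(meta$sample_id)) stop(path, ": missing sample_id metadata line")
  fr <- strsplit(strsplit(meta$aa_freqs, ",")[[1]], ":")
  aaFreqs <- stats::setNames(as.numeric(vapply(fr, `[`, "", 2L)),
                             vapply(fr, `[`, "", 1L))
  df$kmer <- as.character(df$kmer)
  df$k <- as.integer(df$k)
  df$n <- as.integer(df$n)
  df$e <- as.numeric(df$e)
  df$E <- as.numeric(df$E)
  df$F <- as.numeric(df$F)  # an all-NA column would otherwise read as logical
  new("KmerTable", sampleId = meta$sample_id, entries = df,
      aaFreqs = aaFreqs, readCount = as.integer(meta$read_count))
}

#' @rdname tableIO
#' @export
writeBackground <- function(background, path) {
  stopifnot(is(background, "ControlBackground"))
  f <- sdFloor(background)
  floorStr <- if (is.null(names(f))) paste(sprintf("%.15g", f), collapse = ",")
              else paste(sprintf("%s:%.15g", names(f), f), collapse = ",")
  .writeTsv(kmerEntries(background), path,
            meta = list(controls = paste(controlIds(background), collapse = ","),
                        sd_floor = floorStr))
}

#' @rdname tableIO
#' @export
readBackground <- function(path) {
  df <- .readTsv(path, c("kmer", "k", "mean", "sd", "n_controls"))
  meta <- .readTsvMeta(path)
  df$kmer <- as.character(df$kmer)
  df$k <- as.integer(df$k)
  df$n_controls <- as.integer(df$n_controls)
  parts <- strsplit(meta$sd_floor, ",")[[1]]
  if (any(grepl(":", parts, fixed = TRUE))) {
    fl <- strsplit(parts, ":")
    sdFloor <- stats::setNames(as.numeric(vapply(fl, `[`, "", 2L)),
                               vapply(fl, `[`, "", 1L))
  } else {
    sdFloor <- as.numeric(parts)
  }
  new("ControlBackground", controlIds = strsplit(meta$controls, ",")[[1]],
      entries = df, sdFloor = sdFloor)
}

#' @rdname tableIO
#' @export
writeScores <- function(scores, path) {
  .writeTsv(scores[, c("sample_id", "protein_id", "piwas_score", "piwas_loc")], path)
}

#' @rdname tableIO
#' @export
readScores <- function(path) {
  .readTsv(path, c("sample_id", "protein_id", "piwas_score", "piwas_loc"))
}

#' @rdname tableIO
#' @export
writeProteinStats <- function(stats, path) {
  .writeTsv(stats, path)
}

#' @rdname tableIO
#' @export
readProteinStats <- function(path) {
  .readTsv(path, c("protein_id", "outlier_sum", "os_null_mean", "os_null_sd",
                   "os_z", "os_p", "os_fdr", "mw_p", "ks_p", "hedges_g",
                   "loc_ks_p", "dominant_epitopes", "dominant_locs"))
}
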