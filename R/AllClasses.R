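#' @import methods
NULL

## the 20 standard proteinogenic amino-acid letters
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## fixed display-library read length (amino acids)
.READ_LENGTH <- 12L

.validPeptide <- function(x) {
  nchar(x) == .READ_LENGTH & !grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), x)
}

#' PeptideReadSet: one sample's unique 12-mer peptide reads
#'
#' Container for the antibody-selected random-peptide reads of a single
#' specimen: a set of unique 12-residue peptides over the 20 standard
#' amino-acid letters, plus the sample identifier and the number of input
#' lines dropped at load time (wrong length, non-standard letters or
#' duplicates).
#'
#' @slot sampleId single character, the sample identifier.
#' @slot reads character vector of unique valid 12-mers.
#' @slot nDropped integer, count of invalid lines dropped on load.
#'
#' @seealso [loadReads()], [kmerEnrich()]
#' @export
setClass("PeptideReadSet",
  representation(sampleId = "character", reads = "character", nDropped = "integer"),
  prototype(sampleId = NA_character_, reads = character(), nDropped = 0L)
)

setValidity("PeptideReadSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  if (anyDuplicated(object@reads))
    msg <- c(msg, "reads must be unique")
  if (length(object@reads) && !all(.validPeptide(object@reads)))
    msg <- c(msg, sprintf("all reads must be %d-mers over the 20 standard amino-acid letters",
                          .READ_LENGTH))
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideReadSet
#'
#' Builds a read set from a character vector of peptides. Invalid peptides
#' (wrong length or non-standard letters) and duplicates are dropped and
#' counted; pass already-clean reads to avoid the filtering overhead of
#' validation at load time.
#'
#' @param sampleId sample identifier.
#' @param reads character vector of 12-mer peptides.
#' @param filter if `TRUE` (default) drop invalid/duplicate reads with a
#'   message; if `FALSE` the input must already be clean.
#' @return a [PeptideReadSet-class] object.
#' @examples
#' rs <- PeptideReadSet("s1", c("ACDEFGHIKLMN", "ACDEFGHIKLMN", "AAAAAAAAAAAA"))
#' nReads(rs)
#' @export
PeptideReadSet <- function(sampleId, reads, filter = TRUE) {
  nDropped <- 0L
  if (filter) {
    n0 <- length(reads)
    reads <- reads[.validPeptide(reads)]
    reads <- unique(reads)
    nDropped <- n0 - length(reads)
    if (nDropped > 0L)
      message(sprintf("sample %s: dropped %d invalid or duplicate reads", sampleId, nDropped))
  }
  new("PeptideReadSet", sampleId = as.character(sampleId), reads = reads,
      nDropped = as.integer(nDropped))
}

#' KmerTable: per-sample kmer enrichment table
#'
#' Holds, for one sample and kmer sizes k = 5 and 6, the observed unique-read
#' count `n`, the expected count `e` under the sample's amino-acid
#' composition, the enrichment `E = n / e`, and (after normalization against
#' a control background) the z-normalized enrichment `F`. Only observed
#' kmers (`n >= 1`) are materialized by [kmerEnrich()]; unobserved kmers have
#' an implicit enrichment of 0. [normalizeEnrichment()] may add explicit
#' `n = 0` rows for background kmers absent from the sample.
#'
#' @slot sampleId sample identifier.
#' @slot entries data.frame with columns `kmer`, `k`, `n`, `e`, `E`, `F`.
#' @slot aaFreqs named numeric, amino-acid proportions over all read
#'   positions (sums to 1).
#' @slot readCount integer, number of unique 12-mers in the sample.
#'
#' @seealso [kmerEnrich()], [normalizeEnrichment()]
#' @export
setClass("KmerTable",
  representation(sampleId = "character", entries = "data.frame",
                 aaFreqs = "numeric", readCount = "integer")
)

setValidity("KmerTable", function(object) {
  msg <- character()
  need <- c("kmer", "k", "n", "e", "E", "F")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must have columns", paste(need, collapse = ", ")))
  if (length(object@aaFreqs) && abs(sum(object@aaFreqs) - 1) > 1e-9)
    msg <- c(msg, "aaFreqs must sum to 1")
  if (all(need %in% names(object@entries)) && nrow(object@entries)) {
    obs <- object@entries$n >= 1L
    if (any(obs)) {
      with_e <- obs & is.finite(object@entries$e) & object@entries$e > 0
      if (any(abs(object@entries$E[with_e] -
                  object@entries$n[with_e] / object@entries$e[with_e]) >
              1e-9 * pmax(1, object@entries$E[with_e])))
        msg <- c(msg, "E must equal n / e for observed kmers")
    }
    if (!all(object@entries$k %in% c(5L, 6L)))
      msg <- c(msg, "k must be 5 or 6")
  }
  if (length(msg)) msg else TRUE
})

#' ControlBackground: per-kmer control-cohort enrichment background
#'
#' Mean and standard deviation of the enrichment of each kmer across the
#' control cohort, with absence counted as an enrichment of 0 (a kmer not
#' observed in a control contributes E = 0 to that kmer's control vector).
#' Kmers observed in no control are not stored; they have an implicit
#' mean of 0 and sd of 0, which normalization handles through `sdFloor`.
#'
#' @slot controlIds sample identifiers of the controls the background was
#'   built from.
#' @slot entries data.frame with columns `kmer`, `k`, `mean`, `sd`,
#'   `n_controls`.
#' @slot sdFloor positive numeric, one value per kmer size (named by k);
#'   the effective sd used when normalizing a kmer is `max(sd, sdFloor[k])`,
#'   preventing infinite z-scores for near-constant kmers. Floors are per
#'   kmer size because 5-mer and 6-mer enrichments live on very different
#'   scales of variability.
#'
#' @seealso [buildBackground()], [normalizeEnrichment()]
#' @export
setClass("ControlBackground",
  representation(controlIds = "character", entries = "data.frame", sdFloor = "numeric")
)

setValidity("ControlBackground", function(object) {
  msg <- character()
  need <- c("kmer", "k", "mean", "sd", "n_controls")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must have columns", paste(need, collapse = ", ")))
  if (length(object@controlIds) < 2L)
    msg <- c(msg, "a background needs at least 2 controls")
  if (!length(object@sdFloor) || !all(is.finite(object@sdFloor)) ||
      any(object@sdFloor <= 0))
    msg <- c(msg, "sdFloor must be positive")
  if (all(need %in% names(object@entries)) && nrow(object@entries)) {
    if (any(object@entries$sd < 0)) msg <- c(msg, "sd must be non-negative")
    if (!all(object@entries$n_controls == length(object@controlIds)))
      msg <- c(msg, "n_controls must equal the number of controls")
  }
  if (length(msg)) msg else TRUE
})
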