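## Kmer enrichment: decompose 12-mer reads into 5-mers and 6-mers and score
## each kmer's observed unique-read count against its expectation under the
## sample's amino-acid composition.

#' Decompose a 12-mer read into its constituent kmers
#'
#' Returns the `12 - k + 1` consecutive substrings of the read in position
#' order (8 windows for k = 5, 7 for k = 6). Duplicate kmers within the
#' read are retained; per-read uniqueness is the caller's concern.
#'
#' @param read a single 12-residue peptide string.
#' @param k kmer length, 5 or 6.
#' @return character vector of kmers.
#' @examples
#' decomposeRead("ACDEFGHIKLMN", 5)
#' @export
decomposeRead <- function(read, k) {
  stopifnot(length(read) == 1L, nchar(read) == .READ_LENGTH)
  if (!k %in% c(5L, 6L)) stop("k must be 5 or 6")
  starts <- seq_len(.READ_LENGTH - k + 1L)
  substring(read, starts, starts + k - 1L)
}

#' Expected count of a kmer under a sample's amino-acid composition
#'
#' The expected number of unique reads containing the kmer if letters were
#' drawn independently from the sample's composition:
#' `N * (12 - k + 1) * prod(p_i)` where `N` is the number of unique 12-mers
#' and `p_i` the proportion of the kmer's i-th letter among all read
#' positions. Kmers containing a letter never seen in the sample have no
#' finite composition-based expectation and return `NA` with a warning
#' ("inestimable"); such kmers can never be observed in the sample itself.
#'
#' @param kmer kmer string (length 5 or 6).
#' @param readSet a [PeptideReadSet-class], or `NULL` if `aaFreqs` and
#'   `nReads` are given directly.
#' @param aaFreqs named amino-acid proportions (default: computed from
#'   `readSet`).
#' @param nReads number of unique reads (default: from `readSet`).
#' @return positive numeric, or `NA` for inestimable kmers.
#' @examples
#' expectedCount("AAAAA", PeptideReadSet("s", "AAAAAAAAAAAA"))  # 8
#' @export
expectedCount <- function(kmer, readSet = NULL, aaFreqs = NULL, nReads = NULL) {
  k <- nchar(kmer)
  if (!k %in% c(5L, 6L)) stop("k must be 5 or 6")
  if (is.null(aaFreqs)) aaFreqs <- aaFrequencies(readSet)
  if (is.null(nReads)) nReads <- length(readSequences(readSet))
  p <- aaFreqs[strsplit(kmer, "")[[1]]]
  if (anyNA(p) || any(p <= 0)) {
    warning("kmer ", kmer, " contains letters with zero sample proportion; ",
            "expectation inestimable")
    return(NA_real_)
  }
  nReads * (.READ_LENGTH - k + 1L) * prod(p)
}

#' Compute per-kmer enrichment for a sample
#'
#' Decomposes every unique 12-mer into 5-mers and 6-mers and, for each kmer
#' observed at least once, records `n` (the number of unique 12-mers
#' containing the kmer at least once — a kmer occurring twice in one read
#' still counts that read once), the expected count `e` under the sample's
#' amino-acid composition, and the enrichment `E = n / e`. Unobserved kmers
#' are not stored; their enrichment is implicitly 0.
#'
#' @param readSet a [PeptideReadSet-class].
#' @param ks kmer sizes; the method is defined for `c(5, 6)`.
#' @return a [KmerTable-class] covering all requested `ks`.
#' @examples
#' kt <- kmerEnrich(PeptideReadSet("s", c("AAAAAAAAAAAA", "CCCCCCCCCCCC")))
#' head(kmerEntries(kt))
#' @export
kmerEnrich <- function(readSet, ks = c(5L, 6L)) {
  stopifnot(is(readSet, "PeptideReadSet"))
  ks <- as.integer(ks)
  if (!all(ks %in% c(5L, 6L))) stop("k must be 5 or 6")
  seqs <- readSequences(readSet)
  if (!length(seqs)) stop("empty read set")
  N <- length(seqs)
  freqs <- aaFrequencies(readSet)
  logf <- log(freqs)

  per_k <- lapply(ks, function(k) {
    nWin <- .READ_LENGTH - k + 1L
    km <- unlist(lapply(seq_len(nWin), function(s) substr(seqs, s, s + k - 1L)),
                 use.names = FALSE)
    rid <- rep.int(seq_len(N), nWin)  # read index, one block per window start
    dt <- data.table::data.table(kmer = km, rid = rid)
    cnt <- unique(dt)[, list(n = .N), by = "kmer"]
    ## expected counts from position-wise letter log-frequencies
    lp <- numeric(nrow(cnt))
    for (s in seq_len(k)) {
      lp <- lp + logf[substr(cnt$kmer, s, s)]
    }
    e <- N * nWin * exp(lp)
    data.frame(kmer = cnt$kmer, k = k, n = cnt$n, e = unname(e),
               E = cnt$n / unname(e), F = NA_real_, stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, per_k)
  new("KmerTable", sampleId = sampleId(readSet), entries = entries,
      aaFreqs = freqs, readCount = N)
}

#' Query enrichment values from a kmer table
#'
#' Vectorized lookup of `E` (or normalized `F`) for arbitrary kmers of one
#' size; kmers absent from the table return 0 for `E` (unobserved means no
#' enrichment) and `NA` for `F` (absent kmers get their normalized value
#' from the background, see [normalizeEnrichment()]).
#'
#' @param table a [KmerTable-class].
#' @param kmers character vector, all of the same length `k`.
#' @param value `"E"` or `"F"`.
#' @return numeric vector aligned with `kmers`.
#' @export
enrichmentOf <- function(table, kmers, value = c("E", "F")) {
  value <- match.arg(value)
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1L)
  ent <- kmerEntries(table)
  ent <- ent[ent$k == k, ]
  idx <- match(kmers, ent$kmer)
  out <- ent[[value]][idx]
  if (value == "E") out[is.na(idx)] <- 0
  out
}
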