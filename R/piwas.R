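## PIWAS core: tile per-kmer values onto proteins, smooth over a sliding
## window of kmer starts, take the per-protein maximum and its location,
## and extract dominant epitope strings.

## All position-wise kmers of a set of protein sequences for one k.
## Returns the concatenated per-start kmer vector (protein by protein, in
## position order), the per-protein number of starts, and the unique kmers.
.proteomeKmers <- function(sequences, k) {
  lens <- pmax(nchar(sequences) - k + 1L, 0L)
  all <- unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    starts <- seq_len(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  list(all = all, lens = lens, unique = unique(all))
}

.standardKmer <- function(kmers) {
  !grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), kmers)
}

## Per-kmer value under a scoring mode. Kmers absent from the sample have
## E = 0; in normalized mode that zero is still centered and scaled by the
## background. Kmers with non-standard letters are masked to 0: they can
## never be observed in a 12-mer library over the standard alphabet.
.kmerValues <- function(kmers, table, mode, background) {
  if (!length(kmers)) return(numeric())
  std <- .standardKmer(kmers)
  E <- numeric(length(kmers))
  if (any(std)) E[std] <- enrichmentOf(table, kmers[std], "E")
  if (mode == "raw") {
    v <- E
  } else {
    k <- unique(nchar(kmers))
    bg <- kmerEntries(background)
    bg <- bg[bg$k == k, ]
    idx <- match(kmers, bg$kmer)
    mu <- ifelse(is.na(idx), 0, bg$mean[idx])
    sg <- ifelse(is.na(idx), 0, bg$sd[idx])
    v <- (E - mu) / pmax(sg, .sdFloorFor(background, k))
  }
  v[!std] <- 0
  v
}

#' Tile a sample's kmer values along a protein
#'
#' For each kmer size k in {5, 6} and each start position `j` in
#' `1 .. L - k + 1`, looks up the sample's value of the protein kmer at `j`:
#' raw enrichment `E` (0 when unobserved) or control-normalized `F` (the
#' normalized value of E = 0 when unobserved). Windows covering
#' non-standard letters (X, U, B, Z) are masked to 0. Proteins shorter than
#' k yield an empty vector for that k.
#'
#' @param sequence protein sequence string.
#' @param table the sample's [KmerTable-class].
#' @param mode `"normalized"` (default; requires `background`) or `"raw"`.
#' @param background a [ControlBackground-class] for normalized mode.
#' @param ks kmer sizes.
#' @return named list of per-start value vectors, one per k (`"k5"`, `"k6"`).
#' @export
tileProtein <- function(sequence, table, mode = c("normalized", "raw"),
                        background = NULL, ks = c(5L, 6L)) {
  mode <- match.arg(mode)
  if (mode == "normalized" && is.null(background))
    stop("normalized mode requires a control background")
  out <- lapply(as.integer(ks), function(k) {
    L <- nchar(sequence)
    if (L < k) return(numeric())
    starts <- seq_len(L - k + 1L)
    kmers <- substring(sequence, starts, starts + k - 1L)
    .kmerValues(kmers, table, mode, background)
  })
  names(out) <- paste0("k", ks)
  out
}

#' Windowed maximum of tiled kmer values
#'
#' The scoring primitive: given the per-start value vectors for k = 5 and
#' k = 6, the window at start `i` sums, for each k, positions
#' `j = i .. min(i + w, last valid start for that k)`; the score is the
#' maximum window sum over all 5-mer starts and the location is the smallest
#' start attaining it (1-based). Proteins with no valid 5-mer start score 0
#' with location `NA`.
#'
#' @param values5,values6 numeric vectors of per-start values (lengths
#'   `L - 4` and `L - 5`; either may be empty).
#' @param w window width in kmer starts (the window covers `w + 1` starts).
#' @return list with elements `score` and `loc`.
#' @examples
#' piwasWindowMax(c(1, 2, 3), c(10, 20), w = 1)  # score 33 at loc 1
#' @export
piwasWindowMax <- function(values5, values6, w = 5L) {
  stopifnot(w >= 0L)
  n5 <- length(values5)
  n6 <- length(values6)
  if (n5 == 0L) return(list(score = 0, loc = NA_integer_))
  cs5 <- c(0, cumsum(values5))
  cs6 <- c(0, cumsum(values6))
  i <- seq_len(n5)
  s5 <- cs5[pmin(i + w, n5) + 1L] - cs5[i]
  s6 <- cs6[pmin(i + w, n6) + 1L] - cs6[pmin(i - 1L, n6) + 1L]
  tot <- s5 + s6
  loc <- which.max(tot)  # smallest index on ties
  list(score = tot[[loc]], loc = loc)
}

#' PIWAS score of one protein for one sample
#'
#' Tiles the sample's kmer values along the protein ([tileProtein()]) and
#' returns the windowed maximum and its location ([piwasWindowMax()]).
#'
#' @inheritParams tileProtein
#' @param w window width in kmer starts; the default 5 makes dominant
#'   epitopes 11 residues long.
#' @return list with `score` and `loc` (1-based window start).
#' @export
piwasScore <- function(sequence, table, mode = c("normalized", "raw"),
                       background = NULL, w = 5L) {
  mode <- match.arg(mode)
  v <- tileProtein(sequence, table, mode, background)
  piwasWindowMax(v$k5, v$k6, w)
}

#' Score every sample against every protein of a proteome
#'
#' Computes the PIWAS score and location for each (sample, protein) pair.
#' Kmer lookups are batched per sample over the proteome's kmer universe,
#' so cost scales with (proteome kmers + table kmers) per sample rather
#' than per protein. Results are independent of proteome record order.
#'
#' @param proteome proteome data.frame (see [loadProteome()]).
#' @param tables named list of [KmerTable-class], one per sample.
#' @param background a [ControlBackground-class] (required for normalized
#'   mode).
#' @param mode `"normalized"` or `"raw"`.
#' @param w window width.
#' @return long data.frame with columns `sample_id`, `protein_id`,
#'   `piwas_score`, `piwas_loc`.
#' @export
scoreCohort <- function(proteome, tables, background = NULL,
                        mode = c("normalized", "raw"), w = 5L) {
  mode <- match.arg(mode)
  if (mode == "normalized" && is.null(background))
    stop("normalized mode requires a control background")
  pk5 <- .proteomeKmers(proteome$sequence, 5L)
  pk6 <- .proteomeKmers(proteome$sequence, 6L)
  idx5 <- match(pk5$all, pk5$unique)
  idx6 <- match(pk6$all, pk6$unique)
  off5 <- cumsum(c(0L, pk5$lens))
  off6 <- cumsum(c(0L, pk6$lens))
  nP <- nrow(proteome)
  res <- lapply(tables, function(tbl) {
    u5 <- .kmerValues(pk5$unique, tbl, mode, background)
    u6 <- .kmerValues(pk6$unique, tbl, mode, background)
    v5 <- u5[idx5]
    v6 <- u6[idx6]
    score <- numeric(nP)
    loc <- integer(nP)
    for (p in seq_len(nP)) {
      sl5 <- if (pk5$lens[p]) v5[(off5[p] + 1L):off5[p + 1L]] else numeric()
      sl6 <- if (pk6$lens[p]) v6[(off6[p] + 1L):off6[p + 1L]] else numeric()
      sc <- piwasWindowMax(sl5, sl6, w)
      score[p] <- sc$score
      loc[p] <- if (is.na(sc$loc)) NA_integer_ else sc$loc
    }
    data.frame(sample_id = sampleId(tbl), protein_id = proteome$protein_id,
               piwas_score = score, piwas_loc = loc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract the epitope string under a scoring window
#'
#' The window at start `loc` spans `w + 1` 6-mers, i.e. `w + 6` residues
#' (11 for the default `w = 5`); near the protein's C-terminus the span is
#' truncated to the remaining residues.
#'
#' @param sequence protein sequence string.
#' @param loc 1-based window start position within the protein.
#' @param w window width.
#' @return peptide substring of length `min(w + 6, L - loc + 1)`.
#' @examples
#' extractEpitope("ACDEFGHIKLMNPQRS", 3, w = 5)  # "DEFGHIKLMNP"
#' @export
extractEpitope <- function(sequence, loc, w = 5L) {
  L <- nchar(sequence)
  if (is.na(loc) || loc < 1L || loc > L)
    stop("loc must be a valid window start in [1, ", L, "]")
  substr(sequence, loc, min(loc + w + 5L, L))
}

#' Dominant epitopes of a protein across case samples
#'
#' Collects the score locations of case samples exceeding a score
#' threshold, clusters locations within `w` of each other (single linkage
#' on the integer line), and reports each cluster's modal location (ties to
#' the smallest), its epitope string and the number of supporting samples,
#' ordered by support descending (ties by location).
#'
#' @param sequence protein sequence string.
#' @param locs integer vector of case score locations.
#' @param scores numeric vector of case scores, aligned with `locs`.
#' @param threshold minimum score for a sample to support an epitope
#'   (default 6).
#' @param w window width used for scoring.
#' @return data.frame with columns `epitope`, `loc`, `support`; zero rows
#'   when no case exceeds the threshold.
#' @export
dominantEpitopes <- function(sequence, locs, scores, threshold = 6, w = 5L) {
  keep <- !is.na(locs) & scores > threshold
  empty <- data.frame(epitope = character(), loc = integer(), support = integer(),
                      stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  locs <- sort(locs[keep])
  gaps <- which(diff(locs) > w)
  cluster <- rep.int(seq_len(length(gaps) + 1L), diff(c(0L, gaps, length(locs))))
  out <- lapply(split(locs, cluster), function(cl) {
    tab <- table(cl)
    modal <- as.integer(names(tab)[which.max(tab)])  # smallest mode on ties
    data.frame(epitope = extractEpitope(sequence, modal, w), loc = modal,
               support = length(cl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$support, out$loc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
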