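## Control background: per-kmer mean/sd of enrichment across the control
## cohort, and z-normalization of a sample against it.

#' Build a per-kmer enrichment background from control samples
#'
#' For every kmer observed in at least one control, computes the mean and
#' standard deviation of the control enrichment vector, where controls in
#' which the kmer was not observed contribute an enrichment of 0 (absence
#' means no enrichment, so the control vector always has one value per
#' control). Kmers observed in no control are not stored; normalization
#' treats them as mean 0, sd 0 (floored).
#'
#' The sd floor guards against infinite z-scores on near-constant kmers; by
#' default it is the 1st percentile of the strictly positive per-kmer sds of
#' the background, computed separately for each kmer size at build time.
#' Per-size floors matter because 6-mer enrichments are far sparser (hence
#' individually larger and more variable) than 5-mer enrichments: a single
#' shared floor would let chance 6-mer observations that no control happened
#' to make dominate the normalized scale.
#'
#' @param tables list of [KmerTable-class] objects from the control cohort
#'   (at least 2; one control gives no standard deviation).
#' @param proteome optional proteome data.frame (see [loadProteome()]); when
#'   given, the background is restricted to kmers that occur in the proteome,
#'   bounding its size to what scoring can ever use.
#' @param denominator `"sample"` (n - 1, default: sensible for small control
#'   cohorts) or `"population"` (n) standard deviation.
#' @param sdFloor positive numeric to override the automatic floor: either a
#'   single value applied to every kmer size or a vector named by k.
#' @param floorQuantile quantile of positive sds used for the automatic
#'   floor.
#' @return a [ControlBackground-class].
#' @examples
#' rs <- lapply(1:3, function(i)
#'   PeptideReadSet(paste0("c", i), c("ACDEFGHIKLMN", "AAAAAAAAAAAA")))
#' bg <- buildBackground(lapply(rs, kmerEnrich))
#' @export
buildBackground <- function(tables, proteome = NULL,
                            denominator = c("sample", "population"),
                            sdFloor = NULL, floorQuantile = 0.01) {
  denominator <- match.arg(denominator)
  if (length(tables) < 2L)
    stop("need at least 2 control kmer tables to build a background")
  ids <- vapply(tables, sampleId, "")
  nC <- length(tables)
  all <- data.table::rbindlist(lapply(tables, function(t) {
    e <- kmerEntries(t)
    data.table::data.table(kmer = e$kmer, k = e$k, E = e$E)
  }))
  agg <- all[, list(s = sum(E), ss = sum(E^2), nobs = .N), by = c("kmer", "k")]
  if (!is.null(proteome)) {
    keep <- logical(nrow(agg))
    for (k in unique(agg$k)) {
      universe <- .proteomeKmers(proteome$sequence, k)$unique
      keep[agg$k == k] <- agg$kmer[agg$k == k] %in% universe
    }
    agg <- agg[keep]
  }
  mean <- agg$s / nC
  ss_centered <- pmax(agg$ss - nC * mean^2, 0)  # zero-filled control vectors
  dfree <- if (denominator == "sample") nC - 1L else nC
  sd <- sqrt(ss_centered / dfree)
  ks <- sort(unique(as.integer(agg$k)))
  if (!length(ks)) ks <- c(5L, 6L)
  if (is.null(sdFloor)) {
    sdFloor <- vapply(ks, function(k) {
      pos <- sd[agg$k == k & sd > 0]
      f <- if (length(pos)) stats::quantile(pos, floorQuantile, names = FALSE)
           else sqrt(.Machine$double.eps)
      max(f, sqrt(.Machine$double.eps))
    }, 0)
    names(sdFloor) <- ks
  } else {
    sdFloor <- as.numeric(sdFloor)
    if (length(sdFloor) == 1L) sdFloor <- rep(sdFloor, length(ks))
    names(sdFloor) <- ks
  }
  entries <- data.frame(kmer = agg$kmer, k = as.integer(agg$k), mean = mean,
                        sd = sd, n_controls = rep.int(nC, length(mean)),
                        stringsAsFactors = FALSE)
  new("ControlBackground", controlIds = ids, entries = entries,
      sdFloor = sdFloor)
}

## floor for one kmer size, falling back to the first value for sizes the
## background never saw
.sdFloorFor <- function(background, k) {
  f <- background@sdFloor
  key <- as.character(k)
  if (!is.null(names(f)) && key %in% names(f)) unname(f[[key]]) else unname(f[[1L]])
}

#' z-normalize a sample's enrichments against a control background
#'
#' Sets `F = (E - mean) / max(sd, sdFloor)` for every kmer in the union of
#' the sample's observed kmers and the background's kmers; background kmers
#' absent from the sample are added as explicit rows with `n = 0`, `E = 0`
#' (absence is an enrichment of 0). Kmers the background never saw use
#' mean 0, sd 0, so their F is `E / sdFloor`; the count of such
#' degenerate-sd kmers with nonzero E is messaged.
#'
#' @param table a [KmerTable-class].
#' @param background a [ControlBackground-class].
#' @return a [KmerTable-class] with the `F` column filled.
#' @export
normalizeEnrichment <- function(table, background) {
  stopifnot(is(table, "KmerTable"), is(background, "ControlBackground"))
  ent <- kmerEntries(table)
  bg <- kmerEntries(background)
  kk <- sort(unique(c(ent$k, bg$k)))
  out <- lapply(kk, function(k) {
    floor <- .sdFloorFor(background, k)
    s <- ent[ent$k == k, ]
    b <- bg[bg$k == k, ]
    extra <- setdiff(b$kmer, s$kmer)
    if (length(extra)) {
      s <- rbind(s, data.frame(kmer = extra, k = k, n = 0L, e = NA_real_,
                               E = 0, F = NA_real_, stringsAsFactors = FALSE))
    }
    idx <- match(s$kmer, b$kmer)
    mu <- ifelse(is.na(idx), 0, b$mean[idx])
    sg <- ifelse(is.na(idx), 0, b$sd[idx])
    s$F <- (s$E - mu) / pmax(sg, floor)
    ndeg <- sum(sg < floor & s$E != 0)
    if (ndeg > 0L)
      message(sprintf("sample %s, k=%d: %d kmers normalized with floored sd",
                      sampleId(table), k, ndeg))
    s
  })
  entries <- do.call(rbind, out)
  rownames(entries) <- NULL
  new("KmerTable", sampleId = sampleId(table), entries = entries,
      aaFreqs = aaFrequencies(table), readCount = nReads(table))
}
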