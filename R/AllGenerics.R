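#' @include AllClasses.R
NULL

#' Accessors for PIWAS containers
#'
#' `sampleId()` returns the sample identifier; `nReads()` the number of
#' unique 12-mers; `readSequences()` the peptide reads themselves;
#' `kmerEntries()` the kmer-level data.frame of a [KmerTable-class] or
#' [ControlBackground-class]; `controlIds()` and `sdFloor()` the control
#' cohort and sd floor of a background; `aaFrequencies()` the amino-acid
#' proportions (computed for a read set, stored for a kmer table).
#'
#' @param object a PIWAS container.
#' @return the corresponding slot value (see Description).
#' @name accessors
#' @examples
#' rs <- PeptideReadSet("s1", c("ACDEFGHIKLMN", "AAAAAAAAAAAA"))
#' sampleId(rs)
#' nReads(rs)
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("nReads", function(object) standardGeneric("nReads"))

#' @rdname accessors
#' @export
setGeneric("readSequences", function(object) standardGeneric("readSequences"))

#' @rdname accessors
#' @export
setGeneric("kmerEntries", function(object) standardGeneric("kmerEntries"))

#' @rdname accessors
#' @export
setGeneric("controlIds", function(object) standardGeneric("controlIds"))

#' @rdname accessors
#' @export
setGeneric("sdFloor", function(object) standardGeneric("sdFloor"))

#' Amino-acid composition of a read set
#'
#' Proportion of each of the 20 standard amino-acid letters over all 12
#' positions of all unique reads in the sample. These proportions are the
#' `p_i` terms of the expected kmer count under the sample's composition.
#' Letters never seen get a proportion of 0; the vector sums to 1.
#'
#' @param object a [PeptideReadSet-class] (computed) or [KmerTable-class]
#'   (stored at enrichment time).
#' @return named numeric vector of length 20 summing to 1.
#' @examples
#' aaFrequencies(PeptideReadSet("s", "AAAAAAAAAAAA"))["A"]
#' @export
setGeneric("aaFrequencies", function(object) standardGeneric("aaFrequencies"))

setMethod("sampleId", "PeptideReadSet", function(object) object@sampleId)
setMethod("sampleId", "KmerTable", function(object) object@sampleId)
setMethod("nReads", "PeptideReadSet", function(object) length(object@reads))
setMethod("nReads", "KmerTable", function(object) object@readCount)
setMethod("readSequences", "PeptideReadSet", function(object) object@reads)
setMethod("kmerEntries", "KmerTable", function(object) object@entries)
setMethod("kmerEntries", "ControlBackground", function(object) object@entries)
setMethod("controlIds", "ControlBackground", function(object) object@controlIds)
setMethod("sdFloor", "ControlBackground", function(object) object@sdFloor)

setMethod("aaFrequencies", "PeptideReadSet", function(object) {
  if (!length(object@reads)) stop("empty read set: amino-acid frequencies undefined")
  codes <- utf8ToInt(paste(object@reads, collapse = ""))
  counts <- tabulate(codes, nbins = 127L)
  p <- counts[utf8ToInt(paste(.AA20, collapse = ""))]
  p <- p / sum(p)
  names(p) <- .AA20
  p
})

setMethod("aaFrequencies", "KmerTable", function(object) object@aaFreqs)

setMethod("show", "PeptideReadSet", function(object) {
  cat(sprintf("PeptideReadSet '%s': %d unique 12-mer reads (%d dropped at load)\n",
              object@sampleId, length(object@reads), object@nDropped))
})

setMethod("show", "KmerTable", function(object) {
  tab <- table(factor(object@entries$k, levels = c(5L, 6L)))
  cat(sprintf("KmerTable '%s': %d 5-mers, %d 6-mers from %d unique reads%s\n",
              object@sampleId, tab[["5"]], tab[["6"]], object@readCount,
              if (all(is.na(object@entries$F))) " (unnormalized)" else " (normalized)"))
})

setMethod("show", "ControlBackground", function(object) {
  cat(sprintf("ControlBackground: %d kmers over %d controls, sd floor %s\n",
              nrow(object@entries), length(object@controlIds),
              paste(sprintf("%.4g (k=%s)", object@sdFloor,
                            names(object@sdFloor)), collapse = ", ")))
})
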