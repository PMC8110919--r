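## Independent brute-force oracles. These deliberately avoid the package's
## code paths (and data.table): plain loops and hand-written order
## statistics, so that agreement with the implementation is informative.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Brute-force kmer enrichment: nested loops, substring containment via
## grepl, explicit letter counting and product-of-proportions expectation.
oracleEnrich <- function(reads, k) {
  ## amino-acid proportions by literal counting
  letters <- unlist(strsplit(reads, ""))
  p <- sapply(AA20, function(a) sum(letters == a) / length(letters))
  ## all kmers seen anywhere
  kmers <- unique(unlist(lapply(reads, function(r) {
    sapply(1:(nchar(r) - k + 1), function(s) substr(r, s, s + k - 1))
  })))
  n <- sapply(kmers, function(km) sum(grepl(km, reads, fixed = TRUE)))
  e <- sapply(kmers, function(km) {
    prod_p <- 1
    for (a in strsplit(km, "")[[1]]) prod_p <- prod_p * p[[a]]
    length(reads) * (12 - k + 1) * prod_p
  })
  data.frame(kmer = kmers, n = as.integer(n), e = as.numeric(e),
             E = as.numeric(n / e), stringsAsFactors = FALSE, row.names = NULL)
}

## Exhaustive window scan: explicit double summation over k and j for every
## candidate start i, exactly as the score is defined.
oracleWindowScore <- function(v5, v6, w) {
  n5 <- length(v5); n6 <- length(v6)
  if (n5 == 0) return(list(score = 0, loc = NA_integer_))
  best <- -Inf; bestLoc <- NA_integer_
  for (i in 1:n5) {
    tot <- 0
    for (j in i:min(i + w, n5)) tot <- tot + v5[j]
    if (i <= n6) for (j in i:min(i + w, n6)) tot <- tot + v6[j]
    if (tot > best) { best <- tot; bestLoc <- i }
  }
  list(score = best, loc = bestLoc)
}

## Hand-written order statistics (type-7 linear interpolation), median and
## scaled MAD, used by the literal outlier-sum transcription below.
oracleQuantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracleMedian <- function(x) oracleQuantile(x, 0.5)

oracleMad <- function(x) 1.4826 * oracleMedian(abs(x - oracleMedian(x)))

## Literal transcription of the outlier sum: standardize the combined
## sample by median and scaled MAD, fence at q75 + IQR of the standardized
## values, sum the case values strictly above the fence.
oracleOutlierSum <- function(case, control) {
  x <- c(case, control)
  med <- oracleMedian(x)
  m <- oracleMad(x)
  if (m == 0) m <- .Machine$double.eps * max(1, abs(med))
  z <- (x - med) / m
  q25 <- oracleQuantile(z, 0.25)
  q75 <- oracleQuantile(z, 0.75)
  fence <- q75 + (q75 - q25)
  zc <- z[seq_along(case)]
  total <- 0
  for (v in zc) if (v > fence) total <- total + v
  total
}
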