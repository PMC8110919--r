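## Small programmatic fixtures shared across test files.

randomReads <- function(n, seed = NULL, letters = AA20) {
  if (!is.null(seed)) set.seed(seed)
  reads <- character(0)
  while (length(reads) < n) {
    m <- matrix(sample(letters, (n - length(reads)) * 12, replace = TRUE), ncol = 12)
    reads <- unique(c(reads, apply(m, 1, paste, collapse = "")))
  }
  reads
}

randomProtein <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}

## A tiny fully-written cohort on disk: returns the simulateCohort() result.
tinyCohort <- function(dir, seed = 7, ...) {
  ## a minority of planted cases: the outlier sum targets subset signals
  defaults <- list(outDir = dir, nCases = 4L, nControls = 6L,
                   readsPerSample = 400L, nDecoys = 8L, decoyLength = 60L,
                   plantRate = 0.3, prevalence = 0.5, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulateCohort, args)
}
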