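## Synthetic cohorts: SERA-like random 12-mer read sets with planted
## epitope fragments in case samples, plus the magnitude/prevalence power
## experiments that operate directly on PIWAS score vectors.

.randomPeptides <- function(n, aaFreqs) {
  letters <- names(aaFreqs)[aaFreqs > 0]
  probs <- aaFreqs[aaFreqs > 0]
  m <- matrix(sample(letters, n * .READ_LENGTH, replace = TRUE, prob = probs),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## n unique random 12-mers, rejection-resampling duplicates; `avoid` is an
## optional set the result must also be disjoint from.
.uniquePeptides <- function(n, aaFreqs, avoid = character()) {
  nLetters <- sum(aaFreqs > 0)
  if (n > 0.1 * nLetters^.READ_LENGTH)
    stop("readsPerSample exceeds 10% of the sequence space; cannot deduplicate")
  out <- character()
  while (length(out) < n) {
    cand <- .randomPeptides(n - length(out), aaFreqs)
    out <- unique(c(out, setdiff(cand, avoid)))
  }
  out
}

## Reads carrying a contiguous fragment of the epitope: fragment length
## uniform in [minFragment, nchar(epitope)], placed at a uniform offset,
## random flanking letters.
.plantedPeptides <- function(n, epitope, minFragment, aaFreqs) {
  if (n == 0L) return(character())
  epiLen <- nchar(epitope)
  maxFrag <- min(.READ_LENGTH, epiLen)
  lens <- seq.int(minFragment, maxFrag)
  flen <- lens[sample.int(length(lens), n, replace = TRUE)]
  fstart <- vapply(flen, function(fl) sample.int(epiLen - fl + 1L, 1L), 0L)
  offset <- vapply(flen, function(fl) sample.int(.READ_LENGTH - fl + 1L, 1L), 0L)
  flank <- .randomPeptides(n, aaFreqs)
  frag <- substring(epitope, fstart, fstart + flen - 1L)
  paste0(substr(flank, 1L, offset - 1L), frag,
         substring(flank, offset + flen, .READ_LENGTH))
}

#' Generate a synthetic SERA-like cohort with a planted epitope
#'
#' Control samples are sets of unique 12-mers with letters i.i.d. from the
#' background amino-acid composition. A `prevalence` fraction of case
#' samples is "planted": a `plantRate` fraction of their reads carries a
#' contiguous fragment (length uniform between `minFragment` and the
#' epitope length) of the epitope — a substring of one target protein — at
#' a uniform offset, with random flanking residues. Unplanted cases are
#' indistinguishable from controls. Everything (decoy proteome, reads,
#' planted-sample choice) is reproducible from `seed`.
#'
#' What this emulates: the unique-12-mer structure, composition background
#' and subset-of-cases antigen signal of serum antibody screens. What it
#' does not: clonal antibody families, mimotopes, library construction
#' bias or sequencing error.
#'
#' @param outDir directory to write read files, `manifest.tsv`,
#'   `proteome.fasta` (when generated) and `truth.tsv` into.
#' @param nCases,nControls cohort sizes (defaults 20 / 50).
#' @param readsPerSample unique 12-mers per sample (default 2e4; production
#'   screens run at ~1e6+).
#' @param aaFreqs background composition (default uniform over the 20
#'   standard letters).
#' @param proteome optional proteome data.frame to plant into; by default
#'   `nDecoys` random decoy proteins of length `decoyLength` are generated.
#' @param nDecoys,decoyLength decoy proteome shape (defaults 200 x 300).
#' @param epitopeProtein protein id carrying the epitope (default: first
#'   protein).
#' @param epitopeStart 1-based epitope start (default: protein middle).
#' @param epitopeLength epitope length in residues (default 11, the span of
#'   a default-width scoring window).
#' @param plantRate fraction of a planted case's reads carrying an epitope
#'   fragment (signal magnitude proxy; default 0.02).
#' @param prevalence fraction of case samples planted (default 0.5).
#' @param minFragment minimum fragment length (default 5, the shortest
#'   linear stretch an antibody paratope engages).
#' @param seed integer seed.
#' @return list with `manifest` (data.frame), `truth` (data.frame:
#'   `protein_id`, `epitope_start`, `epitope_end`, `sample_id`,
#'   `planted_flag`), `proteome` (data.frame), `proteomePath`, `dir`.
#' @export
simulateCohort <- function(outDir, nCases = 20L, nControls = 50L,
                           readsPerSample = 20000L, aaFreqs = NULL,
                           proteome = NULL, nDecoys = 200L, decoyLength = 300L,
                           epitopeProtein = NULL, epitopeStart = NULL,
                           epitopeLength = 11L, plantRate = 0.02,
                           prevalence = 0.5, minFragment = 5L, seed = 1L) {
  stopifnot(plantRate >= 0, plantRate <= 1, prevalence >= 0, prevalence <= 1,
            minFragment >= 5L, epitopeLength >= minFragment)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  set.seed(as.integer(seed))
  if (is.null(aaFreqs))
    aaFreqs <- stats::setNames(rep(1 / 20, 20), .AA20)
  if (abs(sum(aaFreqs) - 1) > 1e-9) stop("aaFreqs must sum to 1")

  if (is.null(proteome)) {
    seqs <- vapply(seq_len(nDecoys), function(i)
      paste(sample(names(aaFreqs)[aaFreqs > 0], decoyLength, replace = TRUE,
                   prob = aaFreqs[aaFreqs > 0]), collapse = ""), "")
    proteome <- data.frame(
      protein_id = sprintf("SYNP%03d", seq_len(nDecoys)),
      description = sprintf("synthetic decoy protein %d", seq_len(nDecoys)),
      sequence = seqs, length = nchar(seqs), stringsAsFactors = FALSE)
  }
  if (is.null(epitopeProtein)) epitopeProtein <- proteome$protein_id[1L]
  target <- match(epitopeProtein, proteome$protein_id)
  if (is.na(target)) stop("epitopeProtein not in proteome: ", epitopeProtein)
  L <- proteome$length[target]
  if (is.null(epitopeStart))
    epitopeStart <- max(1L, (L - epitopeLength) %/% 2L)
  if (epitopeStart + epitopeLength - 1L > L)
    stop("epitope does not fit inside ", epitopeProtein)
  epitope <- substr(proteome$sequence[target], epitopeStart,
                    epitopeStart + epitopeLength - 1L)

  nPlanted <- round(prevalence * nCases)
  plantedIdx <- if (nPlanted > 0L) sort(sample.int(nCases, nPlanted)) else integer()
  ids <- c(sprintf("case_%02d", seq_len(nCases)),
           sprintf("ctrl_%02d", seq_len(nControls)))
  cohorts <- c(rep("case", nCases), rep("control", nControls))
  planted <- c(seq_len(nCases) %in% plantedIdx, rep(FALSE, nControls))

  paths <- file.path(outDir, paste0(ids, ".txt"))
  for (i in seq_along(ids)) {
    if (planted[i]) {
      nPlant <- round(plantRate * readsPerSample)
      pl <- unique(.plantedPeptides(nPlant, epitope, minFragment, aaFreqs))
      ## rejection-resample duplicates; conclude the fragment space is
      ## saturated only after many consecutive no-progress batches
      stall <- 0L
      while (length(pl) < nPlant && stall < 30L) {
        prev <- length(pl)
        pl <- unique(c(pl, .plantedPeptides(max(nPlant - length(pl), 16L),
                                            epitope, minFragment, aaFreqs)))
        stall <- if (length(pl) == prev) stall + 1L else 0L
      }
      pl <- pl[seq_len(min(length(pl), nPlant))]
      if (length(pl) < nPlant)
        warning(sprintf("sample %s: planted-read space saturated at %d of %d; filling with background reads",
                        ids[i], length(pl), nPlant))
      rnd <- .uniquePeptides(readsPerSample - length(pl), aaFreqs, avoid = pl)
      reads <- c(pl, rnd)
    } else {
      reads <- .uniquePeptides(readsPerSample, aaFreqs)
    }
    writeLines(reads, paths[i])
  }

  ## the written manifest uses basenames, resolved against its own
  ## directory on read; the returned data.frame carries the full paths
  manifest <- data.frame(sample_id = ids, path = paths, cohort = cohorts,
                         stringsAsFactors = FALSE)
  manifestFile <- data.frame(sample_id = ids, path = basename(paths),
                             cohort = cohorts, stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = epitopeProtein,
                      epitope_start = epitopeStart,
                      epitope_end = epitopeStart + epitopeLength - 1L,
                      sample_id = ids, planted_flag = planted,
                      stringsAsFactors = FALSE)
  proteomePath <- file.path(outDir, "proteome.fasta")
  writeProteome(proteome, proteomePath)
  writeManifest(manifestFile, file.path(outDir, "manifest.tsv"))
  .writeTsv(truth, file.path(outDir, "truth.tsv"))
  list(manifest = manifest, truth = truth, proteome = proteome,
       proteomePath = proteomePath, dir = outDir)
}

#' Scale the magnitude of a case score vector
#'
#' Element-wise multiplication of the case PIWAS values by a scaling
#' factor; control values are left untouched by the experiment design.
#'
#' @param caseScores numeric vector.
#' @param factor non-negative scaling factor.
#' @return scaled vector.
#' @export
scaleMagnitude <- function(caseScores, factor) {
  stopifnot(factor >= 0)
  caseScores * factor
}

#' Resample a case score vector to a target signal prevalence
#'
#' Splits the case values into a "high" pool (values strictly above
#' `threshold`; values equal to the threshold go to the low pool) and a
#' "low" pool, then draws a vector of the original size with replacement:
#' each position independently comes from the high pool with probability
#' `prevalence` (or, with `fixedCount = TRUE`, exactly
#' `round(prevalence * n)` positions do).
#'
#' @param caseScores numeric vector.
#' @param prevalence target fraction of high-signal samples in `[0, 1]`.
#' @param threshold high/low split point (default 6).
#' @param fixedCount use a fixed high count instead of independent
#'   Bernoulli draws.
#' @return resampled vector of `length(caseScores)`.
#' @export
resamplePrevalence <- function(caseScores, prevalence, threshold = 6,
                               fixedCount = FALSE) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  high <- caseScores[caseScores > threshold]
  low <- caseScores[caseScores <= threshold]
  n <- length(caseScores)
  if (prevalence > 0 && !length(high)) stop("high pool is empty")
  if (prevalence < 1 && !length(low)) stop("low pool is empty")
  isHigh <- if (fixedCount) {
    seq_len(n) %in% sample.int(n, round(prevalence * n))
  } else {
    stats::runif(n) < prevalence
  }
  out <- numeric(n)
  if (any(isHigh))
    out[isHigh] <- high[sample.int(length(high), sum(isHigh), replace = TRUE)]
  if (any(!isHigh))
    out[!isHigh] <- low[sample.int(length(low), sum(!isHigh), replace = TRUE)]
  out
}

#' Magnitude / prevalence power curves for the outlier sum
#'
#' Reproduces the signal-titration experiment design on a pair of base
#' PIWAS score vectors for one protein: along the magnitude axis, the case
#' values are multiplied by each factor of the grid and the outlier-sum
#' permutation pipeline is run against the unscaled controls; along the
#' prevalence axis, the case vector is resampled `nResamples` times at each
#' target prevalence (high/low split at `highThreshold`) and the per-grid
#' point significance is summarized by the median (with quartiles) across
#' resamples.
#'
#' @param caseScores,controlScores base PIWAS score vectors.
#' @param axis `"magnitude"` or `"prevalence"`.
#' @param grid grid of scaling factors (default `seq(0.1, 2, 0.1)`) or
#'   prevalences (default `seq(0.05, 1, 0.05)`).
#' @param highThreshold high/low split for the prevalence axis (default 6).
#' @param nResamples resamples per prevalence point (default 1000).
#' @param nPerm permutations per outlier-sum null (default 1000).
#' @param seed master seed.
#' @return data.frame with one row per grid point: `grid`, `outlier_sum`,
#'   `os_z`, `os_p`, `neg_log10_os_p` and, for the prevalence axis,
#'   `os_p_q25` / `os_p_q75` across resamples.
#' @export
powerCurve <- function(caseScores, controlScores,
                       axis = c("magnitude", "prevalence"), grid = NULL,
                       highThreshold = 6, nResamples = 1000L, nPerm = 1000L,
                       seed = 1L) {
  axis <- match.arg(axis)
  if (is.null(grid))
    grid <- if (axis == "magnitude") seq(0.1, 2, by = 0.1) else seq(0.05, 1, by = 0.05)
  if (!length(grid)) stop("grid must be non-empty")
  set.seed(as.integer(seed))
  rows <- lapply(grid, function(g) {
    if (axis == "magnitude") {
      pn <- permutationNull(scaleMagnitude(caseScores, g), controlScores,
                            nPerm = nPerm)
      data.frame(grid = g, outlier_sum = pn$outlier_sum, os_z = pn$os_z,
                 os_p = pn$os_p, neg_log10_os_p = pn$neg_log10_p,
                 os_p_q25 = NA_real_, os_p_q75 = NA_real_)
    } else {
      res <- vapply(seq_len(nResamples), function(i) {
        pn <- permutationNull(
          resamplePrevalence(caseScores, g, threshold = highThreshold),
          controlScores, nPerm = nPerm)
        c(pn$outlier_sum, if (pn$degenerate) NA_real_ else pn$os_z,
          pn$os_p, pn$neg_log10_p)
      }, numeric(4))
      q <- stats::quantile(res[3, ], c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
      data.frame(grid = g, outlier_sum = stats::median(res[1, ]),
                 os_z = stats::median(res[2, ], na.rm = TRUE),
                 os_p = q[2], neg_log10_os_p = stats::median(res[4, ]),
                 os_p_q25 = q[1], os_p_q75 = q[3])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
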