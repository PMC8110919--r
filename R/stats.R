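## Cohort comparison statistics: outlier sum with a permutation null and
## normal-tail p-value, Mann-Whitney U, Kolmogorov-Smirnov (scores and
## locations), Hedges' g, Benjamini-Hochberg FDR, and proteome-wide ranking.

## Standardized values and upper fence for the outlier sum, computed from
## the combined case + control sample (both are label-invariant).
.outlierParts <- function(x) {
  med <- stats::median(x)
  m <- stats::mad(x)  # 1.4826 * median absolute deviation
  if (m == 0) m <- .Machine$double.eps * max(1, abs(med))
  z <- (x - med) / m
  q <- stats::quantile(z, c(0.25, 0.75), type = 7, names = FALSE)
  list(z = z, threshold = q[2L] + (q[2L] - q[1L]))
}

#' Outlier sum statistic
#'
#' Standardizes the combined case + control values by the combined median
#' and MAD (scale constant 1.4826), sets the outlier fence at the 75th
#' percentile plus the interquartile range of the standardized values
#' (linear-interpolation quantiles), and returns the sum of the CASE
#' standardized values strictly exceeding the fence. The statistic is
#' sensitive to signals carried by only a subset of cases, unlike
#' mean-shift tests. A zero MAD is floored at a machine-epsilon scale.
#'
#' @param case,control numeric score vectors (`case` non-empty).
#' @return non-negative numeric.
#' @examples
#' outlierSum(c(10, 0, 0), c(0.1, -0.2, 0.05, 0, -0.1, 0.15))
#' @export
outlierSum <- function(case, control) {
  if (!length(case)) stop("case vector must be non-empty")
  parts <- .outlierParts(c(case, control))
  zc <- parts$z[seq_along(case)]
  sum(zc[zc > parts$threshold])
}

#' Permutation null for the outlier sum
#'
#' Permutes case/control labels (uniform re-labelling preserving group
#' sizes) `nPerm` times, recomputing the outlier sum under each labelling,
#' and summarizes the observed statistic against that null: the z-score
#' `(O - mean) / sd` and, because the outlier sum is a sum of exceedances
#' whose null is asymptotically normal, a one-sided upper-tail normal
#' p-value. Standardization and the fence depend only on the combined
#' (label-invariant) sample, so the permuted statistics are subset sums of
#' a precomputed exceedance vector; this is exactly equivalent to
#' recomputing the full statistic per permutation.
#'
#' @param case,control numeric score vectors.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @return list with `outlier_sum`, `null_mean`, `null_sd`, `os_z`, `os_p`,
#'   `neg_log10_p` (underflow-safe `-log10(os_p)`), and `degenerate`
#'   (`TRUE` when every permuted statistic is identical, in which case
#'   `os_p = 1`).
#' @export
permutationNull <- function(case, control, nPerm = 1000L, seed = NULL) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  x <- c(case, control)
  n <- length(x)
  nc <- length(case)
  parts <- .outlierParts(x)
  u <- ifelse(parts$z > parts$threshold, parts$z, 0)
  obs <- sum(u[seq_len(nc)])
  perm <- vapply(seq_len(nPerm), function(i) sum(u[sample.int(n, nc)]), 0)
  mu <- mean(perm)
  sdv <- stats::sd(perm)
  if (sdv == 0) {
    return(list(outlier_sum = obs, null_mean = mu, null_sd = 0,
                os_z = NA_real_, os_p = 1, neg_log10_p = 0, degenerate = TRUE))
  }
  z <- (obs - mu) / sdv
  logp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  list(outlier_sum = obs, null_mean = mu, null_sd = sdv, os_z = z,
       os_p = exp(logp), neg_log10_p = -logp / log(10), degenerate = FALSE)
}

#' Mann-Whitney U p-value (case greater than control)
#'
#' One-sided by default (case stochastically greater): the alternative of
#' interest is elevated scores in cases. Exact when both groups have fewer
#' than 8 observations (and no ties); tie-corrected normal approximation
#' with continuity correction otherwise.
#'
#' @param case,control numeric vectors (both non-empty).
#' @param alternative passed to [stats::wilcox.test()].
#' @param exact override the automatic exact/approximate choice.
#' @return p-value.
#' @export
mannWhitneyP <- function(case, control, alternative = "greater", exact = NULL) {
  if (!length(case) || !length(control)) stop("both groups must be non-empty")
  if (is.null(exact)) exact <- length(case) < 8L && length(control) < 8L
  suppressWarnings(
    stats::wilcox.test(case, control, alternative = alternative,
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Two-sample Kolmogorov-Smirnov p-value
#'
#' Two-sided, asymptotic by default; used both for score distributions and
#' for score-location distributions (locational epitope conservation).
#'
#' @param x,y numeric vectors; `NA`s are dropped.
#' @param exact use the exact distribution (small samples only).
#' @return p-value, or `NA` when either vector is empty after `NA` removal.
#' @export
ksCompareP <- function(x, y, exact = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  suppressWarnings(stats::ks.test(x, y, exact = exact)$p.value)
}

#' Hedges' g effect size
#'
#' Standardized mean difference (case minus control over the pooled sample
#' sd) with the small-sample correction `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#' Returns `NA` with a warning when the pooled sd is zero.
#'
#' @param case,control numeric vectors with at least 2 values in total per
#'   pooled variance requirements.
#' @return numeric effect size.
#' @examples
#' hedgesG(c(4, 5, 6), c(1, 2, 3))  # 2.4
#' @export
hedgesG <- function(case, control) {
  n1 <- length(case)
  n2 <- length(control)
  if (n1 + n2 < 3L) stop("need at least 3 values in total")
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) / (n1 + n2 - 2)
  if (is.na(sp2) || sp2 == 0) {
    if (mean(case) == mean(control)) return(0)
    warning("pooled sd is zero; Hedges' g undefined")
    return(NA_real_)
  }
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  J * (mean(case) - mean(control)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values over all tested proteins; `NA` p-values propagate.
#'
#' @param p vector of p-values.
#' @return q-values of the same length.
#' @export
fdrAdjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

## Deterministic per-protein permutation seed derived from the master seed
## and the protein identifier, so results do not depend on evaluation order.
.proteinSeed <- function(seed, proteinId) {
  codes <- utf8ToInt(proteinId)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) %% 2147480000 + h * 7919) %% 2147483647)
}

#' Rank a proteome by case-versus-control statistics
#'
#' For every protein in the score matrix, compares the case and control
#' PIWAS score distributions: outlier sum with its permutation null
#' ([permutationNull()]), one-sided Mann-Whitney U, two-sided KS on scores,
#' Hedges' g, and a two-sided KS on score locations (locational epitope
#' conservation). Outlier-sum p-values are BH-adjusted across all proteins
#' and the table is sorted by that FDR (ascending), then by outlier-sum z
#' (descending). Proteins whose scores are all zero in both cohorts are
#' reported with p-values of 1 rather than dropped.
#'
#' Per-protein permutation streams are derived deterministically from the
#' master seed and the protein identifier, so the result is independent of
#' protein and sample order.
#'
#' @param scores long score data.frame from [scoreCohort()] or
#'   [readScores()].
#' @param manifest manifest data.frame assigning `sample_id` to cohorts.
#' @param nPerm permutations per protein.
#' @param seed master integer seed.
#' @param proteome optional proteome data.frame; when given, dominant
#'   epitopes of case samples scoring above `scoreThreshold` are reported
#'   per protein (semicolon-joined), see [dominantEpitopes()].
#' @param scoreThreshold dominant-epitope support threshold.
#' @param w window width used for scoring (for epitope extraction).
#' @return data.frame with one row per protein: `protein_id`,
#'   `outlier_sum`, `os_null_mean`, `os_null_sd`, `os_z`, `os_p`, `os_fdr`,
#'   `mw_p`, `ks_p`, `hedges_g`, `loc_ks_p`, `n_case`, `n_control`,
#'   `dominant_epitopes`, `dominant_locs`.
#' @export
rankProteome <- function(scores, manifest, nPerm = 1000L, seed = 1L,
                         proteome = NULL, scoreThreshold = 6, w = 5L) {
  missing <- setdiff(unique(scores$sample_id), manifest$sample_id)
  if (length(missing))
    stop("samples present in scores but not in manifest: ",
         paste(missing, collapse = ", "))
  ## canonical row order: results must not depend on score/manifest row order
  scores <- scores[order(scores$protein_id, scores$sample_id), ]
  cohort <- manifest$cohort[match(scores$sample_id, manifest$sample_id)]
  isCase <- cohort == "case"
  pids <- sort(unique(scores$protein_id))
  seqs <- if (!is.null(proteome))
    stats::setNames(proteome$sequence, proteome$protein_id) else NULL

  rows <- lapply(pids, function(pid) {
    sel <- scores$protein_id == pid
    A <- scores$piwas_score[sel & isCase]
    B <- scores$piwas_score[sel & !isCase]
    Aloc <- scores$piwas_loc[sel & isCase]
    Bloc <- scores$piwas_loc[sel & !isCase]
    if (all(c(A, B) == 0)) {
      row <- data.frame(protein_id = pid, outlier_sum = 0,
                        os_null_mean = 0, os_null_sd = 0, os_z = NA_real_,
                        os_p = 1, mw_p = 1, ks_p = 1, hedges_g = 0,
                        loc_ks_p = 1, stringsAsFactors = FALSE)
    } else {
      pn <- permutationNull(A, B, nPerm = nPerm,
                            seed = .proteinSeed(seed, pid))
      row <- data.frame(protein_id = pid, outlier_sum = pn$outlier_sum,
                        os_null_mean = pn$null_mean, os_null_sd = pn$null_sd,
                        os_z = if (pn$degenerate) NA_real_ else pn$os_z,
                        os_p = pn$os_p,
                        mw_p = mannWhitneyP(A, B),
                        ks_p = ksCompareP(A, B),
                        hedges_g = hedgesG(A, B),
                        loc_ks_p = ksCompareP(Aloc, Bloc),
                        stringsAsFactors = FALSE)
    }
    row$n_case <- length(A)
    row$n_control <- length(B)
    if (!is.null(seqs)) {
      ep <- dominantEpitopes(seqs[[pid]], Aloc, A, threshold = scoreThreshold, w = w)
      row$dominant_epitopes <- paste(ep$epitope, collapse = ";")
      row$dominant_locs <- paste(ep$loc, collapse = ";")
    } else {
      row$dominant_epitopes <- ""
      row$dominant_locs <- ""
    }
    row
  })
  out <- do.call(rbind, rows)
  out$os_fdr <- fdrAdjust(out$os_p)
  out <- out[order(out$os_fdr, -ifelse(is.na(out$os_z), -Inf, out$os_z),
                   out$protein_id), ]
  rownames(out) <- NULL
  out[, c("protein_id", "outlier_sum", "os_null_mean", "os_null_sd", "os_z",
          "os_p", "os_fdr", "mw_p", "ks_p", "hedges_g", "loc_ks_p",
          "n_case", "n_control", "dominant_epitopes", "dominant_locs")]
}

#' Per-sample histogram of scores or enrichments
#'
#' Bins values per sample over a common set of bin edges covering the
#' pooled data range, for distribution-comparison plots (e.g. PIWAS value
#' distributions per cohort). Counts per sample sum to that sample's number
#' of values.
#'
#' @param values numeric vector.
#' @param sampleIds character vector aligned with `values`.
#' @param bins number of equal-width bins, or an explicit vector of edges.
#' @return data.frame with columns `sample_id`, `bin_lo`, `bin_hi`, `count`.
#' @export
distributionSummary <- function(values, sampleIds, bins = 30L) {
  stopifnot(length(values) == length(sampleIds))
  if (length(bins) == 1L) {
    rng <- range(values, finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  } else {
    edges <- bins
  }
  out <- lapply(split(values, sampleIds), function(v) {
    idx <- .bincode(v, edges, include.lowest = TRUE)
    data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
               count = tabulate(idx, nbins = length(edges) - 1L))
  })
  ids <- rep(names(out), each = length(edges) - 1L)
  out <- do.call(rbind, out)
  out <- cbind(sample_id = ids, out)
  rownames(out) <- NULL
  out
}
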