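---
title: "PIWAS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PIWAS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serum antibody repertoires can be profiled by selecting a random-peptide
display library (~10^10 distinct 12-mers) with a serum or plasma specimen and
sequencing the bound peptides. Each specimen yields a set of unique 12-residue
amino-acid reads — typically 10^6 or more in a production screen — whose
composition is shaped by the antibody specificities present in that
individual. A Protein-based Immunome Wide Association Study (PIWAS) turns
these library-space read sets into proteome-space antigen candidates: it asks,
for every protein in a target proteome, whether case specimens carry
systematically stronger linear-epitope signal along that protein than control
specimens do. This package implements that pipeline end to end, together with
a synthetic-cohort generator used to validate it.

## The statistic, stage by stage

**Kmer enrichment.** Each unique 12-mer is decomposed into its constituent
5-mers (8 windows) and 6-mers (7 windows) — long enough to be
antibody-recognizable linear stretches, short enough to be observable at
realistic sequencing depth. For sample $S$ and kmer $m$,

$$E_S(m) = \frac{n_S(m)}{e_S(m)}, \qquad
  e_S(m) = N_S\,(L_{seq} - k + 1) \prod_{i=1}^{k} p_i,$$

where $n_S(m)$ counts the unique 12-mers containing $m$ at least once, $N_S$
is the number of unique 12-mers, $L_{seq} = 12$, and $p_i$ is the proportion
of $m$'s $i$-th letter among all read positions of the sample. Only observed
kmers are materialized; an unobserved kmer has enrichment 0. Because the read
sets are deduplicated at load, both $n_S$ and $N_S$ count unique reads — the
two counters must use the same universe for $E$ to be a ratio of like
quantities.

**Control normalization.** For every kmer, the control cohort supplies a
reference distribution: the vector of control enrichments (zero-filled for
controls that never observed the kmer, one value per control) has mean
$\mu(C)$ and standard deviation $\sigma(C)$, and a sample is normalized as
$F_S(m) = (E_S(m) - \mu(C))/\sigma(C)$. We use the $n-1$ (sample) standard
deviation by default because desk-scale control cohorts are small; the $n$
denominator is available via `denominator = "population"`.

**Scoring by tiling.** For protein $p$ and sample $s$, kmer values
($G_S = F_S$ by default, $E_S$ in raw mode) are tiled along the protein and
smoothed over a sliding window of $w + 1$ kmer starts, adding the 5-mer and
6-mer contributions:

$$P(s,p) = \max_i \sum_{k=5}^{6}\ \sum_{j=i}^{\min(i+w,\ L-k+1)} G_S(m(j,k,p)),$$

with $P_{loc}(s,p)$ the smallest window start attaining the maximum
(determinism under ties). The upper summation limit is the last valid start
for each $k$, which resolves the boundary off-by-one a literal reading of the
window sum would create at the protein's C-terminus; window starts beyond the
last valid 5-mer start are excluded because they contribute only empty sums.

**Cohort comparison.** Per protein, the case and control score vectors are
compared with: the outlier sum (standardize the combined scores by median and
1.4826-scaled MAD, fence at $q_{75} + \mathrm{IQR}$ of the standardized
values with linear-interpolation quantiles, sum the case values strictly
above the fence); a permutation null of 1,000 label permutations summarized
by $z = (O - \mu_{O^0})/\sigma_{O^0}$ with a one-sided upper-tail normal
p-value; a one-sided Mann-Whitney U (cases greater); a two-sided KS on
scores; Hedges' g; and a two-sided KS on score *locations*, which flags
proteins whose case epitopes are positionally conserved. Outlier-sum
p-values are Benjamini-Hochberg adjusted across all proteins and the table
is ranked by that FDR. The outlier sum, not a mean-shift test, carries the
ranking because autoantigen signal is typically present in only a subset of
cases; the one-sided reading follows from its construction (it accumulates
case-upward exceedances only).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ks` | 5, 6 | kmer sizes tiled onto the proteome |
| `window` ($w$) | 5 | smoothing window in kmer starts; $w+1$ 6-mers span $w+6 = 11$ residues, so reported dominant epitopes are 11-mers |
| `mode` | `normalized` | score on control-normalized $F$; `raw` scores on $E$ |
| `n_perm` | 1000 | label permutations per protein |
| `sd_floor` | automatic | per-kmer-size floor on $\sigma(C)$, see below |
| `score_threshold` | 6 | minimum score for a case to support a dominant epitope |
| `min_reads_warn` | 10,000 | unique-read count below which loading warns (production screens run at $\ge 10^6$; the warning, not an error, keeps desk-scale data usable) |

The window width is the one genuinely free geometric parameter; $w = 5$ makes
the reported epitope exactly 11 residues, the length of the dominant-epitope
peptides such screens report, and is exposed as a parameter rather than a
constant.

## Numerical and degenerate-input choices

- **Positions are 1-based** throughout the R API and all reports.
- **Ties in the argmax** go to the smallest window start.
- **Non-standard proteome letters** (X, U, B, Z) zero every window covering
  them: a 12-mer library over the 20 standard letters can never observe such
  kmers, so they carry no evidence.
- **Proteins shorter than 5 residues** score 0 with location `NA`.
- **Zero MAD** in the outlier sum is floored at machine-epsilon scale;
  all-constant inputs yield an outlier sum of 0.
- **Degenerate permutation nulls** (every permuted statistic identical)
  report p = 1 with a flag rather than NaN; proteins whose scores are all
  zero in both cohorts are reported with p = 1 rather than dropped, keeping
  the output schema stable.
- **The sd floor is per kmer size**: the default is the 1st percentile of
  the strictly positive per-kmer control sds, computed separately for 5-mers
  and 6-mers. The two sizes live on very different scales — at a given read
  depth the 6-mer space is roughly 20-fold sparser, so expected counts are
  smaller and singleton enrichments correspondingly larger and more
  variable. A single shared floor (necessarily set by the dense 5-mer
  scale) would turn chance 6-mer observations of kmers no control happened
  to see into enormous z-scores for non-control samples only, a systematic
  case-versus-control artifact at desk-scale depth. Per-size floors keep a
  background-absent singleton on the same normalized scale as an
  in-background singleton.
- **Values exactly at the high/low split** in the prevalence experiment go
  to the low pool (the split is defined by strict inequalities, leaving
  equality unassigned; assigning it low is the conservative choice).
- **Per-protein permutation streams** are derived deterministically from the
  master seed and the protein identifier, so results are independent of
  protein evaluation order and of sample row order.

## The synthetic cohort generator

`simulateCohort()` emulates the *structure* of antibody-selected read sets:
unique 12-mers, an amino-acid composition background (uniform by default),
and — in a configurable fraction of case samples (`prevalence`) — a
configurable fraction of reads (`plantRate`) carrying a contiguous fragment
(minimum 5 residues, the shortest paratope-engageable linear stretch) of one
planted epitope at a uniform offset with random flanks. The decoy proteome is
drawn from the same composition. Everything is reproducible bit for bit from
the seed.

It deliberately does **not** model: clonal antibody families and their
correlated kmer spectra, mimotopes (structural epitopes without linear
sequence identity), library construction bias, codon-level composition skew,
or sequencing error. Passing the recovery tests therefore demonstrates that
the pipeline's statistics and bookkeeping are correct, not that real serum
screens reach any particular sensitivity.

Defaults (20 cases, 50 controls, 2 × 10^4 reads per sample, 200 decoy
proteins of 300 residues, plant rate 0.02, prevalence 0.5) are the
study-scale conditions used by the end-to-end validation suite; they keep a
full pipeline run to minutes on one CPU while leaving the kmer space sparse
enough to exercise the absence-handling paths that production-depth data
would not.

## The titration experiments

`powerCurve()` perturbs a pair of base PIWAS score vectors for one protein.
Along the magnitude axis, case values are multiplied by factors in
$[0.1, 2]$ and the outlier-sum permutation pipeline is rerun against
unscaled controls. Along the prevalence axis, case values are split into
"high" (score > 6) and "low" pools and resampled with replacement so that
each position is high with the target probability; 1,000 resamples per grid
point are summarized by the median and quartiles of the p-value (the
per-point aggregation is not dictated by the experiment's definition; the
median is robust and the quartile band preserves the spread). Per-position
independent Bernoulli mixing matches "sampling with replacement" most
directly; a fixed-count mode is available. Because the original cohort
behind the published titration is not distributable, the suite generates
synthetic base vectors — a lognormal background with a minority of
moderately high case values — whose structure mirrors a subset-of-cases
antigen signal sitting just above the high/low split. The signal must be
*moderate* for the magnitude axis to be informative: the outlier sum is
invariant to jointly rescaling data, and a signal orders of magnitude above
the fence stays above it across the whole factor grid.

## Known limitations

- With tens rather than thousands of controls, control samples are
  normalized against a background their own enrichments helped define,
  while cases are out-of-sample; a slight case-upward tail on null proteins
  remains even with per-size sd floors. At production control-cohort sizes
  this asymmetry is negligible; at desk scale it is visible and is part of
  why validation uses planted signals well above it.
- The permutation z of the outlier sum saturates: when $m$ case values are
  extreme, the null mean and sd are driven by the same $m$ values, bounding
  $z$ near $\sqrt{m\,(1-f)/f}$ for case fraction $f$ regardless of how
  extreme they are. Ranking among strongly detected proteins is therefore
  more stable than the z values themselves.
- The CLT p-value for the outlier-sum z is approximate; calibration on
  heavy-tailed null scores is close to, but not exactly, uniform.
- One score and one location per (sample, protein): multi-epitope proteins
  report only the dominant window per sample, with secondary epitopes
  surfacing solely through the location clustering across samples.
- No motif discovery, no covariate adjustment, no structural-epitope
  modelling.

## Validation strategy

The test suite checks every computational pillar against an independent
oracle: enrichment against a nested-loop substring counter, the window
maximum against an exhaustive scan, the outlier sum against a literal
step-by-step transcription of its definition (agreement to 10^-12), control
self-normalization against the exact mean-0/sd-1 identity, p-value
calibration on null cohorts, planted-epitope recovery end to end at the
study-scale defaults, monotonicity of both titration axes, and byte-level
reproducibility of a full pipeline run from one seed.
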