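---
title: "Methods: periodicity screening, CCS signatures and match-FDR control"
author: "CellCycleSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: periodicity screening, CCS signatures and match-FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CellCycleSig)
```

# The experimental design being modeled

The pipeline assumes an asynchronous cell population fixed and FACS-sorted
into 16 ordered biochemical states (P1–P16) spanning one cell cycle, from
early G1 through S, G2 and the mitotic subphases to mitotic exit. Each of
four biological replicates is measured in two technical LC–MS repeats, giving
128 samples. Because the populations are ordered states rather than time
points, a series built by concatenating the four replicates of one technical
repeat (replicate-major, population-minor; 64 points) is a
*pseudotimecourse*: a periodic protein completes exactly one cycle per 16
consecutive points, i.e. four cycles per series.

Two consequences drive the statistics:

* A protein oscillating once per cell cycle concentrates its periodogram
  power at Fourier index k = 4 of the 64-point series — frequency 4/64 =
  1/16. Proteins peaking twice per cycle appear at 1/8. The PsP frequency
  filter admits exactly these two frequencies.
* The two technical repeats are independent realizations of the same
  biological series, so requiring the periodicity call in *both* acts as a
  replication filter that suppresses false positives multiplicatively.

# Periodicity testing

## Normalization and assembly

Intensities are scaled per sample to parts per million (sum 10^6), removing
total-abundance (depth) differences exactly. Zeros are treated as missing, the
label-free convention: a zero in these tables means "not quantified", not
"absent". `assemblePseudotimecourses()` requires the full 16 × 4 × 2 design
and errors with the names of any absent design cells.

## Handling missing values

The testing criterion for a series is **completeness ≥ 95%** (at most 3 of 64
points missing), with remaining gaps imputed by the series mean. The mean is
neutral for the periodogram of a centered series, so this preserves the
exact-test null far better than zero-imputation, which would inject spurious
power at all frequencies from what are really left-censored values. Proteins
untestable in either repeat cannot be PsPs. The 95% threshold is a declared
package choice: the originating study design does not pin down its
completeness rule, and the threshold trades test validity (few imputed
points) against coverage. It is a `pipelineConfig()` parameter.

## Fisher's exact g test

For a mean-centered series of length N = 64 the periodogram has
m = ⌊(N−1)/2⌋ = 31 ordinates. Under Gaussian white noise the ordinates are
asymptotically iid exponential, and the maximum-to-sum ratio g has the exact
tail `P(g > x) = Σ_{j=1}^{⌊1/x⌋∧m} (−1)^{j−1} C(m,j) (1−jx)^{m−1}`. Numerical
notes:

* The alternating sum is evaluated with terms computed in log space
  (`lchoose` + `(m−1)·log1p(−jg)`) and accumulated with their signs; the
  result is clipped to [0, 1]. At m = 31 the largest term magnitude stays
  below ~1, so cancellation is benign; the log-space form keeps the binomial
  coefficients from overflowing for larger m.
* g ≤ 1/m forces p = 1; constant series are degenerate and flagged
  untestable rather than tested.
* Exact ties in the argmax are broken toward the smaller index — the longer
  period — so the dominant-frequency filter is deterministic.

The test suite validates the closed form against a 10^5-draw Monte-Carlo null
at m = 7 and m = 31 (the two series lengths used anywhere in the package) at
the 0.5, 0.9 and 0.99 null quantiles, within three Monte-Carlo standard
errors. The noise in the generator is log-normal, not Gaussian; at CV 0.2 the
periodogram ordinates are close enough to their asymptotic behavior that the
observed per-repeat type-I rate at α = 0.05 stays within [0.04, 0.06] (tested
on a 5000-protein null proteome).

## Multiple testing

q-values are computed per repeat across testable proteins: π₀ is estimated on
the λ grid 0.05–0.95 with a cubic smoothing spline (df = 3) evaluated at
λ = 0.95 and clipped to (0, 1], then `q_i = π₀ · min_{p_j ≥ p_i} (n·p_j /
rank_j)`. With fewer than 100 p-values the π₀ fit is unstable and the
function falls back to π₀ = 1 — plain Benjamini–Hochberg — with a warning.
The PsP criterion is q < 0.10 *and* dominant frequency ∈ {1/16, 1/8}, both
conditions in both repeats; applying the frequency condition symmetrically in
both repeats is the package's reading of an ambiguous convention, chosen to
match the symmetry of the q condition.

# Clustering and degron enrichment

PsP profiles are averaged over all 8 replicate series per population (plain
mean over nonmissing values — technical and biological replicates weighted
equally, as the flat averaging convention) and z-scaled to mean 0, sd 1.
Clustering is agglomerative Ward on Euclidean distances of the scaled
profiles (`ward.D2`, i.e. squared-Euclidean updates with distances on the
Euclidean scale; the dialect is stated because implementations differ).
Clustering has no random initialization and is deterministic; partitions are
invariant under input order.

The elbow diagnostic reports within-cluster sum of squares for k = 2–10 and
the maximum-curvature k. "No strong elbow" is declared when the largest
single-step drop is below five times the median step drop — structureless
data decline smoothly and fail this test, while template-structured profiles
exceed it by two orders of magnitude. Cluster labels are then permuted into
temporal order of the cluster-mean peak population (ties to the earliest
member), replacing manual dendrogram-leaf swapping with a reproducible rule.

Motif scanning uses a restricted pattern dialect — literals, `.`, and
bracketed classes over the 20 amino acids — compiled to regular expressions
in which a wildcard can only match a standard residue, so `X`/`B`/`Z`
characters never satisfy a motif (they warn instead). Defaults: KEN `KEN`,
D-box `R..L`, ABBA `F.[ILV][FHY].[DE]` (the canonical literature consensus;
the motif is named but not spelled out as a pattern in the originating
study). Two deliberate omissions: no disorder filtering (SLiMsearch-style
disorder scoring needs an external predictor, so frequencies here are
sequence-only and slightly higher than disorder-filtered ones), and the
enrichment background is **all tested proteins**, not the whole proteome —
self-contained and matching the in-cluster versus detected-background
framing. Enrichment is a one-sided exact hypergeometric test (enrichment
only, which is what the cluster biology predicts), significant at p < 0.01.

# The CCS signature

Signature construction z-scales each PsP across the 128 samples; residual
missing values in these near-complete proteins are set to the scaled mean
(zero). PCA is centered, unscaled (features are already z-scaled), and
SVD-based. Sign conventions: PC1 is flipped if needed so interphase samples
(populations 1–8) score positive; PC2 keeps its arbitrary sign. The "wheel"
property — populations ordered by angle in the PC1/PC2 plane recover the true
cyclic order — is scored by `circularRankCor()`, which maximizes the Spearman
correlation over all rotations and both directions, since a wheel has neither
origin nor handedness.

k-NN classification is Euclidean with k = 6. The training set is all six
series of three biological replicates (96 samples) and the test set the
remaining replicate (32 samples); the replicate granularity is the package's
resolution of an ambiguous convention — splitting by biological replicate
keeps technical repeats of the same biological sample from straddling the
train/test boundary. Vote ties break toward the label with the smallest mean
neighbor distance, then the lowest population index; the reference `class`
implementation breaks ties at random, which is why the classifier is
implemented here and cross-checked against `class::knn` on tie-free cases.

The 16 populations are aggregated into 8 CCSs by k-means on the 16 mean
profiles: 100 restarts under a fixed seed, restarts producing empty clusters
discarded, best inertia kept. States are relabeled by the circular mean
position of their member populations, so a wrap-around state (P16 + P1,
mitotic exit flowing into early G1) sorts at the end of the cycle rather than
mid-sequence. Temporal contiguity of member blocks is *reported*
(`contiguous` slot), not enforced — k-means does not guarantee it, and
forcing it would hide a genuinely non-contiguous solution.

Query assignment computes Spearman's ρ against each CCS profile over
pairwise-complete signature proteins. Rank correlation makes the assignment
invariant to any monotone transform of the query — essential when queries mix
SILAC ratios, label-free ratios and other scales. Queries overlapping fewer
than 30 signature proteins are refused (at n = 30 the t approximation of ρ
is serviceable and correlations are stable); "significant" assignment is
defined as Benjamini–Hochberg-adjusted p < 0.05 across the batch on the
one-sided t-approximate test of the best ρ, reported alongside the raw
coefficients — a concrete operationalization of "high and significant
correlation".

# Match-between-runs FDR

The estimator normalizes by matched *fractions* of features per run, so
target and decoy runs of different sizes compare correctly; users with equal
feature counts can read it as a count ratio. Multiple decoy runs (e.g.
dimethylated and isopropylated) are averaged after per-decoy normalization.
σ per error dimension is 1.4826 × MAD about the median: the matched-error
distribution is a mixture of narrow true matches and broad false matches, and
the MAD ignores the broad tail that would inflate a standard-deviation
estimate. Filtering keeps matches inside center ± 2.5σ (retention time) and
± 3σ (m/z difference, m/z error), boundary inclusive; filtered matches revert
to unmatched so all downstream fractions recompute consistently. With purely
Gaussian errors the three windows retain (2Φ(2.5)−1)(2Φ(3)−1)² ≈ 98.2% of
true matches.

# The synthetic-data generator

The generator is the package's ground truth and its defaults *are* the study
conditions: 16 × 4 × 2 design, 2% periodic proteins, amplitudes uniform on a
1.5–4-fold band, noise CV 0.2, depth CV 0.15, and MNAR missingness with the
logistic midpoint at the 2% abundance quantile (slope 3 per natural-log
unit), emulating a high-completeness MS1-matched dataset. Periodic proteins
follow one of five raised-cosine templates peaking in early interphase, at
G1/S, in S/G2, in mid-mitosis and in late mitosis — in log-abundance each is
a pure tone at one cycle per 16 populations, giving cluster-recovery tests an
exact answer. Baselines are log-normal over ~4 orders of magnitude. The noise
CV and missingness defaults are stand-ins — the statistical shape of real
label-free noise is not recoverable from summary descriptions — and are
configurable precisely because of that.

What the generator does **not** emulate: peptide-level quantitation and
rollup, correlated noise between co-eluting proteins, batch drift across the
FACS sort days, template shapes beyond single-peak raised cosines (no sharp
degradation cliffs), and decoy-escape artifacts in match tables (N-terminal
acetylated or C-terminal arginine peptides that evade chemical modification).
Passing tests therefore demonstrate that the *statistical machinery* is
correct and calibrated under the declared generative model, not that any
particular real dataset would yield a specific PsP list.

Determinism: every generator takes a seed and restores the caller's RNG
state; the pipeline fans one master seed into independent per-stage
substreams so adding a stage never perturbs another stage's draws.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run at the sizes the analyses are
designed for: 5000-protein proteomes (the detected-proteome scale) for
recovery and type-I checks, 10^5 Monte-Carlo draws for the exact-null
validation, 5 × 10^4 features per match-table run, and 200 assignment trials
with 50% missingness at noise σ = 0.5 in scaled units. Smaller fixtures (600–
800 proteins, generous periodic fractions) back the unit tests where
per-protein power, not prevalence, is what matters.

# Interface

The package follows the Bioconductor convention that the exported functions,
`runPipeline()` + `pipelineConfig()`/`readPipelineConfig()` (YAML), and this
vignette are the user interface; there is no shell executable. All stage
outputs are plain TSV/JSON so downstream tooling in any language can consume
them.

# Known limitations

* The exact g null assumes iid Gaussian noise; heavy-tailed or autocorrelated
  noise will miscalibrate p-values. The type-I property test bounds the
  miscalibration under the generator's log-normal noise only.
* Storey's π₀ smoothing needs hundreds of p-values; small screens silently
  become BH (with a warning), which is conservative.
* Motif enrichment without disorder filtering overcounts buried motif
  instances; reported frequencies are sequence-level upper bounds.
* The Spearman assignment presumes the query covers a reasonably unbiased
  subsample of the signature; a query censored *by abundance* correlated with
  cell-cycle phase could bias ρ in ways the overlap guard does not detect.
* The FDR ratio estimator assumes decoy features have the same false-match
  propensity as target features; chemistry-specific decoy escapes violate
  this slightly and are not modeled.
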