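---
title: "Stability-based selection of class-discovery methods for copy-number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-based selection of class-discovery methods for copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghstability)
```

## The model

A *class-discovery method* for array-CGH data is a triple: an input data
representation, a dissimilarity measure between tumor samples, and a
clustering algorithm. No external labels exist with which to score a
candidate clustering, so this package scores methods by **stability**: a
method is applied independently to two overlapping random subsamples of the
cohort, and the two partitions are compared on the samples they share. A
method whose partitions survive subsampling is reproducible in a way a
method chasing noise is not.

Formally, for one method and a fixed number of clusters $k$, draw $M$ pairs
of subsets, each of size $\lfloor r \cdot n \rfloor$ without replacement
(resampling rate $r$); subsets may overlap, both within and across pairs.
Cluster each subset, compare the two partitions of pair $i$ on their common
samples with a pair-counting coefficient, and record the similarity
$S_i \in [0,1]$. With a threshold $s_0$, the Bernoulli variables
$Y_i = I(S_i \ge s_0)$ have rate $p$, estimated by
$\hat p = \frac{1}{M}\sum_i Y_i$. Because the subsets overlap, the $Y_i$
are *dependent*; empirically (and verifiably by simulation — see the
acceptance suite) the mean of the $Y_i$ is still well approximated by a
Gaussian for moderate $M$, so a standardized comparison of rates across
methods remains valid.

Given $K$ methods with rates $\hat p_1, \dots, \hat p_K$ computed on the
*same* subset pairs, the null hypothesis that all methods share one rate is
tested with the homogeneity statistic

$$T = \sum_{k=1}^{K}
  \left( \frac{\hat p_k - \bar p}{\sqrt{\bar p (1 - \bar p)/M}} \right)^2
  \;\sim\; \chi^2_{K-1},
  \qquad \bar p = \tfrac1K \sum_k \hat p_k .$$

If the test is significant the method with the smallest $\hat p$ (ties:
smaller mean similarity, then input order) is excluded and the test is
repeated on the remainder; the loop stops at the first non-significant test
or when one method remains. The sequence of tests is corrected for
multiplicity by Holm's step-down rule: with at most $K-1$ tests possible,
the $t$-th raw p-value is scaled by $K-t$ and the adjusted values are made
monotone non-decreasing. The surviving methods are the **stable set**.
When $\bar p$ is 0 or 1 every rate is equal and $T = 0$ by definition.

Two edge conventions are deliberate and isolated in the code:

* **Jaccard 0/0** — if both partitions restricted to the overlap are fully
  singleton, the Jaccard numerator and denominator are both zero; the
  agreement is defined as 1 (the partitions agree vacuously).
* **Degenerate subsets** — if a method cannot be built on a subset (e.g.
  its minimal-region set is empty at the requested support threshold), the
  pair scores 0 and the failure is logged. Stability is meant to penalise
  fragile representations, not to skip them.

## Representations

* **calls / logratio / smoothed logratio** — every probe is a feature.
  Calls take values in $\{-1, 0, 1, 2\}$ (loss, normal, gain,
  amplification); logratios are base-2 log scale. Smoothed logratios are a
  *pass-through*: segmentation itself (e.g. adaptive-weights smoothing) is
  out of scope and accepted as a precomputed input.
* **PCA** — principal components of the sample × probe logratio matrix
  (probes centered, not scaled — logratios share a scale, and scaling would
  inflate flat probes), keeping the smallest set of components whose
  cumulative explained variance reaches `var_fraction` (default 0.90).
* **minimal regions (MR)** — a minimal region is a maximal run of
  contiguous probes within one chromosome over which a subset of samples
  (its *support*) all carry the same non-normal call. Maximality means
  extending the interval by one probe on either side strictly shrinks the
  support and no strictly larger interval has the identical support; a
  one-step check suffices because supports are antitone in the interval.
  Regions with support below `ceiling(fraction × n)` are dropped; the
  benchmark sweeps fractions 0.05–0.50 in steps of 0.05. Gain (1) and
  amplification (2) are kept as distinct alteration types throughout. The
  representation is the binary sample × region membership matrix.

## Dissimilarity measures

Euclidean and Manhattan row distances and the Pearson dissimilarity
$1 - r$ apply to any feature representation. Three measures are specific to
called copy-number data and apply only to the calls and MR representations:

* `sim` counts pairs of overlapping, same-type altered segments between two
  samples (on MR features: regions supporting both samples). Its raw
  diagonal is the sample's own segment count, which a pair can exceed — one
  long run of $x$ may overlap several runs of $y$. The correction replaces
  each diagonal entry by its row maximum, after which self-similarity
  dominates every row. `sim` is left unnormalized: the max-minus conversion
  to a dissimilarity makes the scale irrelevant to clustering ranks.
* `agree` is the fraction of probes with identical calls, `conc` the
  fraction of probe pairs ordered concordantly
  ($\mathrm{sign}(x_p - x_q) = \mathrm{sign}(y_p - y_q)$, sign in
  $\{-,0,+\}$). Both lie in $[0,1]$ with unit diagonal. `conc` is computed
  from joint call-category counts in $O(L^2)$ per sample pair ($L \le 4$
  call levels) rather than scanning all $O(P^2)$ probe pairs; a brute-force
  scan is kept as the test oracle. Both are implemented for hard calls;
  probabilistic-call weighting is out of scope because the pipeline's
  inputs are hard calls.

Similarities convert to dissimilarities by subtraction from the matrix
maximum with the diagonal forced to zero; Pearson uses its canonical
$1 - r$ instead.

## Clustering algorithms

Complete, average (UPGMA), weighted (WPGMA) and Ward agglomeration are
standard Lance–Williams updates (`stats::hclust`; Ward in the ward.D2
convention, i.e. on squared dissimilarities, since inputs are general
dissimilarities rather than Euclidean distances). Divisive analysis uses
`cluster::diana`. `k`-means (Lloyd, best of 10 seeded restarts by WCSS)
applies to feature representations under Euclidean geometry only;
degenerate inputs with fewer distinct rows than clusters are handled by
promoting surplus duplicates to singleton clusters. `k`-centroids adapts
the scheme to arbitrary dissimilarities: medoids minimise average
within-cluster dissimilarity, assignment/update alternate to a fixed point,
and a greedy medoid-swap refinement escapes the local optima the
alternating scheme can reach; restarts are seeded and the best run by total
dissimilarity to medoids is kept. tsvq and hybrid divisive algorithms are
not implemented.

`total` linkage, associated only with `agree` and `conc`, merges at each
step the pair of clusters whose union is *tightest*, tightness being the
minimum pairwise similarity among members. The published description of
this scheme emphasises that it favours tight clusters without giving a
reproducible formula, so this operationalisation is a documented design
choice, isolated behind the function contract with ties broken by the
smallest cluster-index pair (deterministic).

## Pre-processing

Sex chromosomes are excluded on load; probes are sorted by chromosome and
position. Missing values (real cohorts carry 3–13%) are imputed
deterministically per sample and chromosome: a missing **call** takes the
value of the nearest observed probe by genomic distance (ties to the lower
genome index), and missing **logratios** are linearly interpolated in
position with constant extrapolation at chromosome ends. The rationale is
the spatial coherence of copy number — neighboring genomic segments tend to
be altered in the same way. Imputation is idempotent and never alters an
observed entry. The loader reports the missing fraction of each dataset.

## Synthetic cohorts

`generate_call_dataset()` plants latent classes into an otherwise normal
call matrix: samples are assigned round-robin to `n_clusters` classes, each
class owns `regions_per_cluster` contiguous probe intervals (disjoint
across classes, with a one-probe buffer so planted regions can never fuse),
set to a sampled alteration type for all members. Each entry is then
corrupted to a different random call with probability `noise_rate` and
masked missing with probability `missing_rate`.
`calls_to_logratios()` maps calls to diploid log2 means (−1 → −1, 0 → 0,
1 → log2(3/2), 2 → log2(4/2) = 1; amplification modelled as four copies,
configurable) plus Gaussian noise.

Defaults (48 samples, 2000 probes, 22 autosomes, 3 classes, 5% call noise,
8% missing) mirror the scale of published BAC array-CGH tumor cohorts
(tens of arrays, ~2000–3000 probes). What the generator does **not**
emulate: spatial autocorrelation of noise, normal-cell contamination
diluting the signal, platform-specific artifacts, and class-overlapping
alterations. Tests passing on these cohorts therefore demonstrate the
correctness and calibration of the machinery, not performance claims about
any particular clinical dataset.

```{r example, eval = FALSE}
cfg <- synthetic_config(n_samples = 24, n_probes = 400, n_chromosomes = 8,
                        n_clusters = 3, noise_rate = 0.3,
                        missing_rate = 0.05, region_length = c(8L, 15L),
                        seed = 42)
ds    <- generate_call_dataset(cfg)
data  <- cgh_dataset(calls = impute_missing(ds$profile))
methods <- list(method_spec("mr", "sim", "average", mr_fraction = 0.2),
                method_spec("calls", "euclidean", "ward"))
pairs   <- draw_subset_pairs(24, m_pairs = 50, rate = 0.8, seed = 1)
records <- lapply(methods, evaluate_method_stability, data = data, k = 3,
                  pairs = pairs, seed = 1)
chi2_select_stable(records, s0 = 0.97)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m_pairs` (M) | 100 | subset pairs per stability record; 100 gives $\hat p$ a resolution of 0.01 |
| `rate` (r) | 0.8 | subsample fraction; the protocol sweeps 0.5–0.9 |
| `k` | 2–10 | clusters per partition; tested per k, not pooled |
| `s0` | 0.97 | similarity threshold defining a "reproduced" solution; sweep 0.85–0.99 |
| `alpha` | 0.05 | level of the Holm-corrected iterative test |
| `mr_fraction` | 0.05–0.50 | MR support threshold as a cohort fraction (`ceiling(fraction × n)`) |
| `var_fraction` | 0.90 | PCA cumulative explained-variance target |

All stochastic components (subset draws, k-means/k-centroids restarts,
generator) take explicit seeds; per-pair seeds are derived from the master
seed, so records and the benchmark grid rerun bit-identically.

## Numerical and design choices

* The variance of the dependent-Bernoulli mean is estimated by the pooled
  binomial form $\bar p(1-\bar p)/M$; its adequacy under overlap is checked
  empirically by the Gaussian-approximation experiment in the acceptance
  suite (batched resampling; skewness of the batch rates) rather than by a
  runtime variance estimator.
* Holm correction runs over the iteration sequence of the removal loop
  (one test per iteration, at most $K-1$), not over methods within one
  iteration.
* Measure–representation compatibility is enforced at `method_spec()`
  construction: `sim`/`agree`/`conc` pair only with calls or MR; `kmeans`
  demands Euclidean feature geometry; `total` demands `agree`/`conc`.
  Incompatible grid cells are skipped with a logged reason.
* Interval logic uses 0-based half-open probe-index intervals on the genome
  order; file positions are 1-based bp.
* Agglomerative tie-breaking follows `stats::hclust`'s deterministic order
  rather than an explicit smallest-index rule; all documented examples are
  tie-free.

## Test problem sizes

The oracle-equivalence suites run the brute-force enumerators on 100 random
cohorts of up to 8 samples × 20 probes (minimal regions) and 6 × 14 (sim,
conc). Test calibration uses 200 replicates of K = 5 simulated records at
M = 100; the Gaussian-approximation check uses 5000 resampling pairs (50
batches of M = 100) on a fixed 16-sample cohort; the end-to-end recovery
experiment uses a 60-sample, 400-probe, 3-class cohort with one 5–8-probe
region per class, where the clean cohort yields exact recovery and perfect
stability and 20% call noise measurably degrades the mean agreement. These
sizes were chosen as the smallest at which each property is sharply
testable.

## Known limitations

* The stable set is relative to the methods supplied: the test compares
  rates among candidates and cannot certify a lone method in isolation
  (K = 1 is vacuously stable).
* With $\hat p$ pinned at 0 or 1 for all methods the test has no power by
  construction; choose $s_0$ within the observed similarity range.
* `total` linkage follows this package's tightness definition (see above);
  other implementations of the same idea may order merges differently.
* Real-cohort conclusions require real cohorts; the synthetic generator
  validates machinery, and smoothed logratios must be produced upstream by
  a segmentation tool.
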