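# cghstability

Stability-based selection of class-discovery methods for DNA copy-number
(array-CGH) profiles.

## The problem

Array-CGH measures DNA copy number along the genome as log2 ratios of tumor
versus reference signal, typically discretized per probe into calls: loss
(−1), normal (0), gain (1), amplification (2). Discovering tumor classes
from such profiles requires three choices — an input data representation, a
dissimilarity measure between samples, and a clustering algorithm — and the
combination (a *class-discovery method*) strongly affects the classes
found. Copy-number data differ from expression data: the signal range is
small and discrete, and neighboring probes tend to be altered together, so
generic choices are not obviously right.

`cghstability` compares class-discovery methods by the *stability* of
their solutions: a method applied to two overlapping random subsamples of
the same cohort should produce near-identical partitions of the shared
samples. The package implements

- **representations** — all-probes calls/logratios/smoothed logratios, PCA
  compression (components covering ≥ 90% of variance), and *minimal
  regions* (MR): maximal runs of contiguous probes sharing one non-normal
  call across a sample subset (the region's *support*), binarized into a
  sample × region membership matrix;
- **dissimilarities** — Euclidean, Manhattan, Pearson (1 − r), and the
  copy-number-specific similarities `sim` (count of overlapping same-type
  altered segments, with a diagonal correction so self-similarity dominates
  each row), `agree` (probability of identical calls at a random probe) and
  `conc` (probability of concordant ordering over random probe pairs),
  converted to dissimilarities by subtraction from the matrix maximum;
- **clustering** — complete/average/weighted/Ward agglomerative linkage,
  divisive `diana`, `k`-means, `k`-centroids (medoids on arbitrary
  dissimilarities), and `total` linkage for called data (merges the pair of
  clusters whose union has maximal minimum within-cluster similarity);
- **stability testing** — for each method, M pairs of subsets (resampling
  rate r, drawn without replacement) are clustered into k groups and
  compared on their overlap with the Jaccard, simple-matching or
  Rogers–Tanimoto coefficient, giving similarities S_1..S_M. With
  Y_i = I(S_i ≥ s0) and p̂ = mean(Y), the methods' rates are compared by an
  iterative χ² homogeneity test that remains valid under dependent
  (overlapping) resamplings: under H0 all K methods share one rate, and

      T = Σ_k ( (p̂_k − p̄) / sqrt( p̄(1−p̄)/M ) )²  ~  χ²(K−1),

  with p̄ the pooled rate. While the Holm-adjusted p-value is significant,
  the method with the smallest p̂ is removed and the test repeated; the
  surviving methods are the declared **stable set**;
- **synthetic data** — a generator of call/logratio cohorts with planted
  classes (contiguous altered regions per class), call noise and missing
  values, so the whole pipeline is testable without external data;
- **benchmarking** — `run_benchmark()` sweeps representations × measures ×
  algorithms over k, rates, coefficients and thresholds and summarises how
  often each component appears among stable methods.

## Worked example

```r
library(cghstability)

cfg <- synthetic_config(n_samples = 24, n_probes = 400, n_chromosomes = 8,
                        n_clusters = 3, noise_rate = 0.3, missing_rate = 0.05,
                        region_length = c(8L, 15L), seed = 42)
ds    <- generate_call_dataset(cfg)
calls <- impute_missing(ds$profile)
data  <- cgh_dataset(calls = calls)

methods <- list(method_spec("mr", "sim", "average", mr_fraction = 0.2),
                method_spec("calls", "agree", "average"),
                method_spec("calls", "euclidean", "ward"),
                method_spec("calls", "conc", "kcentroids"))
pairs   <- draw_subset_pairs(24, m_pairs = 50, rate = 0.8, seed = 1)
records <- lapply(methods, function(m)
  evaluate_method_stability(data, m, k = 3, pairs = pairs, seed = 1))

sel <- chi2_select_stable(records, s0 = 0.97)
sel
#> <stability_selection> k=3, jaccard, s0=0.97: 1 of 4 methods stable
#> # A tibble: 4 × 5
#>   method                 mean p_hat stable removed_iteration
#>   <chr>                 <dbl> <dbl> <lgl>              <int>
#> 1 mr0.20+sim+average    0.880  0.6  TRUE                  NA
#> 2 calls+conc+kcentroids 0.685  0.24 FALSE                  3
#> 3 calls+agree+average   0.664  0.24 FALSE                  2
#> 4 calls+euclidean+ward  0.492  0.06 FALSE                  1
sel$iterations
#> # A tibble: 3 × 7
#>   iteration n_methods statistic    df      p_value       p_holm removed
#>       <int>     <int>     <dbl> <int>        <dbl>        <dbl> <chr>
#> 1         1         4      37.8     3 0.0000000317 0.0000000952 calls+euclidean+ward
#> 2         2         3      18.8     2 0.0000848    0.000170     calls+agree+average
#> 3         3         2      13.3     1 0.000265     0.000265     calls+conc+kcentroids
```

On this noisy three-class cohort the minimal-region representation with the
corrected `sim` similarity and average linkage reproduces its partition in
60% of subset pairs at Jaccard ≥ 0.97 (mean agreement 0.88), while the
generic calls/Euclidean/Ward combination manages 6%; the iterative test
removes the three weaker methods one by one and declares the MR-based
method the only stable one. `tidy()`, `glance()` and `autoplot()` work on
the records and the selection; `run_benchmark()` scales the same protocol
to a full method grid.

A thin command-line front end with `simulate` / `stability` / `select` /
`benchmark` subcommands is installed at `inst/cli/cgh-stability`.

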