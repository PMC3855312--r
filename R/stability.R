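#' Draw pairs of overlapping sample subsets
#'
#' Resampling scheme for stability measurement: each subset is a uniform
#' draw of `floor(rate * n)` sample indices without replacement; subsets of
#' a pair (and across pairs) may overlap. Reproducible from `seed`.
#'
#' @param n Cohort size.
#' @param m_pairs Number of pairs M (default 100).
#' @param rate Resampling rate in (0, 1].
#' @param seed Integer seed.
#' @return A tibble with columns `pair`, `idx_a`, `idx_b` (list-columns of
#'   integer indices).
#' @export
draw_subset_pairs <- function(n, m_pairs = 100L, rate = 0.8, seed = 1L) {
  stopifnot(rate > 0, rate <= 1, m_pairs >= 1)
  size <- floor(rate * n)
  if (size < 2) abort("subset size floor(rate * n) must be at least 2")
  draws <- withr::with_seed(seed, {
    lapply(seq_len(2L * m_pairs), function(i) sort(sample.int(n, size)))
  })
  tibble(pair = seq_len(m_pairs),
         idx_a = draws[seq(1L, 2L * m_pairs, by = 2L)],
         idx_b = draws[seq(2L, 2L * m_pairs, by = 2L)])
}

#' Agreement between two partitions
#'
#' Pair-counting agreement of two partitions restricted to their common
#' samples. Over all unordered pairs of common samples, `n11` counts pairs
#' co-clustered in both partitions, `n00` pairs separated in both, and
#' `n10`/`n01` mixed pairs. Jaccard = n11/(n11+n10+n01) (1 when the
#' denominator is 0, i.e. both partitions are fully singleton), simple
#' matching = (n11+n00)/N, Rogers-Tanimoto = (n11+n00)/(n11+n00+2(n10+n01)).
#'
#' @param p,q `cgh_partition`s (named integer vectors); at least two common
#'   sample names are required.
#' @param coefficient `"jaccard"`, `"simple_matching"` or
#'   `"rogers_tanimoto"`.
#' @return A similarity in \[0, 1\].
#' @export
partition_agreement <- function(p, q, coefficient = c("jaccard",
                                                      "simple_matching",
                                                      "rogers_tanimoto")) {
  coefficient <- match.arg(coefficient)
  common <- intersect(names(p), names(q))
  if (length(common) < 2) abort("fewer than 2 common samples")
  a <- p[common]
  b <- q[common]
  co_a <- outer(a, a, `==`)[upper.tri(diag(length(a)))]
  co_b <- outer(b, b, `==`)[upper.tri(diag(length(b)))]
  n11 <- sum(co_a & co_b)
  n00 <- sum(!co_a & !co_b)
  nmix <- sum(co_a != co_b)
  switch(coefficient,
         jaccard = if (n11 + nmix == 0) 1 else n11 / (n11 + nmix),
         simple_matching = (n11 + n00) / (n11 + n00 + nmix),
         rogers_tanimoto = (n11 + n00) / (n11 + n00 + 2 * nmix))
}

#' Measure the stability of one class-discovery method
#'
#' For each pair of overlapping subsamples, the method's representation is
#' re-fit on each subset independently (minimal regions are re-extracted
#' and PCA is re-fit), each subset is clustered into `k` groups, and the
#' two partitions are compared on the overlapping samples with the chosen
#' agreement coefficient. A subset on which the method degenerates (e.g. an
#' empty minimal-region set) scores 0 for that pair and is logged:
#' stability should penalise fragile representations.
#'
#' @param data A `cgh_dataset`; imputed on entry if missing values remain.
#' @param method A [method_spec()].
#' @param k Number of clusters.
#' @param pairs Optional tibble from [draw_subset_pairs()] (share it across
#'   methods so they face identical resamplings); drawn internally
#'   otherwise.
#' @param coefficient Agreement coefficient (default `"jaccard"`).
#' @param m_pairs,rate,seed Used when `pairs` is NULL; `seed` also derives
#'   per-pair seeds for stochastic clusterers.
#' @return A `stability_record`: the M similarities, their mean, the method
#'   and settings, and the number of degenerate pairs. `tidy()` returns the
#'   per-pair similarities, `glance()` a one-row summary.
#' @export
evaluate_method_stability <- function(data, method, k, pairs = NULL,
                                      coefficient = "jaccard",
                                      m_pairs = 100L, rate = 0.8,
                                      seed = 1L) {
  stopifnot(inherits(data, "cgh_dataset"), inherits(method, "cgh_method"))
  coefficient <- match.arg(coefficient, c("jaccard", "simple_matching",
                                          "rogers_tanimoto"))
  if (dataset_has_missing(data)) data <- dataset_impute(data)
  ids <- dataset_samples(data)
  if (is.null(pairs)) {
    pairs <- draw_subset_pairs(length(ids), m_pairs = m_pairs, rate = rate,
                               seed = seed)
  }
  m_pairs <- nrow(pairs)
  pair_seeds <- make_seeds(seed + method$seed, 2L * m_pairs)
  sims <- numeric(m_pairs)
  failures <- character(0)
  for (i in seq_len(m_pairs)) {
    res <- tryCatch({
      pa <- build_partition(dataset_subset(data, ids[pairs$idx_a[[i]]]),
                            method, k, seed = pair_seeds[2L * i - 1L])
      pb <- build_partition(dataset_subset(data, ids[pairs$idx_b[[i]]]),
                            method, k, seed = pair_seeds[2L * i])
      partition_agreement(pa, pb, coefficient)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("pair %d: %s", i,
                                      conditionMessage(res)))
      sims[i] <- 0
    } else {
      sims[i] <- res
    }
  }
  if (length(failures) > 0) {
    warn(paste0(method$label, ": ", length(failures),
                " degenerate pair(s) scored 0"))
  }
  structure(list(method = method, k = as.integer(k),
                 coefficient = coefficient, similarities = sims,
                 mean = mean(sims), m_pairs = m_pairs,
                 rate = attr(pairs, "rate") %||% rate,
                 failures = failures),
            class = "stability_record")
}

dataset_has_missing <- function(data) {
  any(vapply(Filter(Negate(is.null),
                    data[c("calls", "logratio", "smoothed")]),
             function(p) anyNA(profile_matrix(p)), logical(1)))
}

#' @export
print.stability_record <- function(x, ...) {
  cat(sprintf("<stability_record> %s, k=%d, %s: mean %.3f over %d pairs\n",
              x$method$label, x$k, x$coefficient, x$mean, x$m_pairs))
  invisible(x)
}

#' @export
tidy.stability_record <- function(x, ...) {
  tibble(method = x$method$label, k = x$k, coefficient = x$coefficient,
         pair = seq_len(x$m_pairs), similarity = x$similarities)
}

#' @export
glance.stability_record <- function(x, ...) {
  tibble(method = x$method$label, k = x$k, coefficient = x$coefficient,
         m_pairs = x$m_pairs, mean = x$mean,
         sd = stats::sd(x$similarities), n_failures = length(x$failures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
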