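#' Declare the stable set of class-discovery methods
#'
#' Iterative chi-square homogeneity test on the per-method Bernoulli rates
#' of high-similarity events, valid when the resampled subsets overlap
#' (dependent pairs). For each method the M pairwise-solution similarities
#' S_i are thresholded into Y_i = I(S_i >= s0), whose mean p_hat estimates
#' the method's probability of reproducing its solution. Under the null
#' hypothesis that all current methods share one rate, the pooled rate
#' p_bar estimates it, Z_k = (p_hat_k - p_bar) / sqrt(p_bar (1 - p_bar) / M)
#' is asymptotically standard normal (the mean of the dependent Bernoulli
#' variables is empirically Gaussian for large M), and T = sum Z_k^2
#' follows a chi-square distribution with K - 1 degrees of freedom. If the
#' Holm-adjusted p-value is significant the method with the smallest p_hat
#' (ties: lower mean similarity, then input order) is excluded and the test
#' is repeated; the loop stops at the first non-significant test or when a
#' single method remains. The surviving methods are the stable set.
#'
#' Holm's step-down correction is applied over the sequence of tests in the
#' removal loop: the t-th raw p-value is scaled by (K - t), where K - 1 is
#' the maximum number of tests, and adjusted p-values are made monotone
#' non-decreasing. When p_bar is 0 or 1 all rates are equal and T = 0.
#'
#' @param records List of `stability_record`s (one per method; same k,
#'   coefficient and number of pairs).
#' @param s0 Similarity threshold in (0, 1) (default 0.97).
#' @param alpha Significance level (default 0.05).
#' @return A `stability_selection` with components `methods` (tibble:
#'   label, mean, p_hat, stable flag, removal iteration), `iterations`
#'   (tibble: iteration, n_methods, statistic, df, p_value, p_holm,
#'   removed) and the settings. `tidy()` returns the per-method table,
#'   `glance()` a one-row summary.
#' @export
chi2_select_stable <- function(records, s0 = 0.97, alpha = 0.05) {
  stopifnot(s0 > 0, s0 < 1, length(records) >= 1)
  if (inherits(records, "stability_record")) records <- list(records)
  ks <- unique(vapply(records, function(r) r$k, integer(1)))
  coefs <- unique(vapply(records, function(r) r$coefficient, character(1)))
  ms <- unique(vapply(records, function(r) r$m_pairs, integer(1)))
  if (length(ks) > 1 || length(coefs) > 1 || length(ms) > 1) {
    abort("records mix k, coefficient or number of pairs")
  }
  m_pairs <- ms
  labels <- vapply(records, function(r) r$method$label, character(1))
  means <- vapply(records, function(r) r$mean, numeric(1))
  p_hat <- vapply(records, function(r) mean(r$similarities >= s0),
                  numeric(1))

  n_methods <- length(records)
  active <- seq_len(n_methods)
  max_tests <- max(n_methods - 1L, 1L)
  iterations <- list()
  removed_at <- rep(NA_integer_, n_methods)
  prev_adj <- 0
  t <- 0L
  while (length(active) > 1L) {
    t <- t + 1L
    kk <- length(active)
    p_bar <- mean(p_hat[active])
    if (p_bar <= 0 || p_bar >= 1) {
      stat <- 0
      p_raw <- 1
    } else {
      z <- (p_hat[active] - p_bar) / sqrt(p_bar * (1 - p_bar) / m_pairs)
      stat <- sum(z^2)
      p_raw <- stats::pchisq(stat, df = kk - 1L, lower.tail = FALSE)
    }
    adj <- min(1, max(prev_adj, (max_tests - t + 1L) * p_raw))
    prev_adj <- adj
    significant <- adj <= alpha
    drop_idx <- NA_integer_
    if (significant) {
      ord <- order(p_hat[active], means[active], active)
      drop_idx <- active[ord[1]]
    }
    iterations[[t]] <- tibble(
      iteration = t, n_methods = kk, statistic = stat, df = kk - 1L,
      p_value = p_raw, p_holm = adj,
      removed = if (is.na(drop_idx)) NA_character_ else labels[drop_idx])
    if (!significant) break
    removed_at[drop_idx] <- t
    active <- setdiff(active, drop_idx)
  }
  methods <- tibble(
    method = labels, mean = means, p_hat = p_hat,
    stable = seq_len(n_methods) %in% active,
    removed_iteration = removed_at)
  methods <- methods[order(-methods$mean), , drop = FALSE]
  structure(list(methods = methods,
                 iterations = if (length(iterations)) {
                   dplyr::bind_rows(iterations)
                 } else {
                   tibble(iteration = integer(), n_methods = integer(),
                          statistic = numeric(), df = integer(),
                          p_value = numeric(), p_holm = numeric(),
                          removed = character())
                 },
                 stable_set = labels[active], s0 = s0, alpha = alpha,
                 k = ks, coefficient = coefs, m_pairs = m_pairs),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf(paste0("<stability_selection> k=%d, %s, s0=%.2f: %d of %d",
                     " methods stable\n"),
              x$k, x$coefficient, x$s0, length(x$stable_set),
              nrow(x$methods)))
  print(x$methods)
  invisible(x)
}

#' @export
tidy.stability_selection <- function(x, ...) x$methods

#' @export
glance.stability_selection <- function(x, ...) {
  tibble(k = x$k, coefficient = x$coefficient, s0 = x$s0, alpha = x$alpha,
         m_pairs = x$m_pairs, n_methods = nrow(x$methods),
         n_stable = length(x$stable_set),
         n_iterations = nrow(x$iterations))
}
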