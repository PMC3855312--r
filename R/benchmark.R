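#' Expand a grid of compatible class-discovery methods
#'
#' Crosses representations, measures and algorithms, keeping only
#' compatible triples (see [method_spec()]); the minimal-region
#' representation is expanded once per support fraction. Incompatible
#' combinations are skipped and recorded in the `skipped` attribute with a
#' reason.
#'
#' @param representations Character vector of representations.
#' @param measures Character vector of measures.
#' @param algorithms Character vector of algorithms.
#' @param mr_fractions Support fractions for `"mr"` (default the 5-50%
#'   sweep in steps of 5%).
#' @param pca_var PCA variance fraction.
#' @return A list of `cgh_method` objects, named by label, with attribute
#'   `skipped` (tibble of dropped combinations and reasons).
#' @export
expand_method_grid <- function(representations = REPRESENTATIONS,
                               measures = MEASURES,
                               algorithms = ALGORITHMS,
                               mr_fractions = seq(0.05, 0.50, by = 0.05),
                               pca_var = 0.90) {
  grid <- expand.grid(representation = representations, measure = measures,
                      algorithm = algorithms, stringsAsFactors = FALSE)
  methods <- list()
  skipped <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ok <- method_compatible(g$representation, g$measure, g$algorithm)
    if (!isTRUE(ok)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(representation = g$representation, measure = g$measure,
               algorithm = g$algorithm, reason = ok)
      next
    }
    fracs <- if (g$representation == "mr") mr_fractions else NA_real_
    for (f in fracs) {
      m <- method_spec(g$representation, g$measure, g$algorithm,
                       mr_fraction = if (is.na(f)) 0.2 else f,
                       pca_var = pca_var)
      methods[[m$label]] <- m
    }
  }
  structure(methods,
            skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
              tibble(representation = character(), measure = character(),
                     algorithm = character(), reason = character()))
}

#' Run the stability benchmark grid
#'
#' Reproduces the full experimental protocol on one or more cohorts: for
#' every (dataset, resampling rate, k) cell the same M subset pairs are
#' faced by every method; each method's stability record is computed, and
#' for every (k, coefficient, s0) combination the iterative chi-square test
#' declares a stable set. Frequency tables of representations, measures and
#' algorithms among the stable methods are derived per dataset (all k
#' pooled), per k (all datasets pooled), and for full combinations.
#'
#' @param datasets Named list of `cgh_dataset`s.
#' @param methods List of `cgh_method`s (e.g. from [expand_method_grid()]).
#' @param k Integer vector of cluster counts (default 2:10).
#' @param coefficients Agreement coefficients (default `"jaccard"`).
#' @param s0 Similarity thresholds (default 0.97).
#' @param rates Resampling rates (default 0.8).
#' @param m_pairs Number of subset pairs M (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; per-cell seeds are derived from it.
#' @param out_dir Optional directory: writes the grid TSV, per-cell
#'   selection JSONs, frequency TSVs and a manifest.
#' @return A `cgh_benchmark` list: `grid` (tidy tibble with one row per
#'   method x cell: mean, p_hat, stable flag), `selections` (list of
#'   `stability_selection`), `frequencies` (list of tibbles), `skipped`.
#' @export
run_benchmark <- function(datasets, methods = expand_method_grid(),
                          k = 2:10, coefficients = "jaccard", s0 = 0.97,
                          rates = 0.8, m_pairs = 100L, alpha = 0.05,
                          seed = 1L, out_dir = NULL) {
  stopifnot(length(datasets) >= 1, length(methods) >= 1)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  datasets <- lapply(datasets, function(d) {
    if (dataset_has_missing(d)) dataset_impute(d) else d
  })
  grid_rows <- list()
  selections <- list()
  cell_seed <- 0L
  for (ds_name in names(datasets)) {
    data <- datasets[[ds_name]]
    n <- length(dataset_samples(data))
    for (rate in rates) {
      for (kk in k) {
        cell_seed <- cell_seed + 1L
        pairs <- draw_subset_pairs(n, m_pairs = m_pairs, rate = rate,
                                   seed = seed + cell_seed)
        attr(pairs, "rate") <- rate
        for (coef in coefficients) {
          records <- lapply(methods, function(m) {
            evaluate_method_stability(data, m, kk, pairs = pairs,
                                      coefficient = coef,
                                      seed = seed + cell_seed)
          })
          for (s in s0) {
            sel <- chi2_select_stable(records, s0 = s, alpha = alpha)
            key <- sprintf("%s_rate%g_k%d_%s_s%g", ds_name, rate, kk,
                           coef, s)
            selections[[key]] <- sel
            tab <- sel$methods
            grid_rows[[length(grid_rows) + 1L]] <- tibble(
              dataset = ds_name, rate = rate, k = kk, coefficient = coef,
              s0 = s, method = tab$method,
              representation = vapply(methods[tab$method],
                                      function(m) m$representation, ""),
              mr_fraction = vapply(methods[tab$method],
                                   function(m) m$mr_fraction, 0),
              measure = vapply(methods[tab$method],
                               function(m) m$measure, ""),
              algorithm = vapply(methods[tab$method],
                                 function(m) m$algorithm, ""),
              mean = tab$mean, p_hat = tab$p_hat, stable = tab$stable)
          }
        }
      }
    }
  }
  grid <- dplyr::bind_rows(grid_rows)
  freqs <- list(
    by_dataset = stable_frequencies(grid, c("dataset")),
    by_k = stable_frequencies(grid, c("k")),
    combinations = stable_frequencies(grid, character(0), full = TRUE))
  res <- structure(list(grid = grid, selections = selections,
                        frequencies = freqs,
                        skipped = attr(methods, "skipped"),
                        settings = list(k = k, coefficients = coefficients,
                                        s0 = s0, rates = rates,
                                        m_pairs = m_pairs, alpha = alpha,
                                        seed = seed)),
                   class = "cgh_benchmark")
  if (!is.null(out_dir)) write_benchmark(res, out_dir)
  res
}

# frequency of each representation / measure / algorithm among stable
# methods, within the given grouping
stable_frequencies <- function(grid, by, full = FALSE) {
  stable <- dplyr::filter(grid, .data$stable)
  if (full) {
    return(dplyr::arrange(
      dplyr::count(stable, .data$representation, .data$measure,
                   .data$algorithm, name = "n_stable"),
      dplyr::desc(.data$n_stable)))
  }
  long <- tidyr::pivot_longer(
    stable[, c(by, "representation", "measure", "algorithm"), drop = FALSE],
    cols = c("representation", "measure", "algorithm"),
    names_to = "component", values_to = "value")
  dplyr::count(long, dplyr::across(dplyr::all_of(c(by, "component",
                                                   "value"))),
               name = "n_stable")
}

#' @export
print.cgh_benchmark <- function(x, ...) {
  cat("<cgh_benchmark>", nrow(x$grid), "grid rows;",
      length(x$selections), "selection cells\n")
  invisible(x)
}

write_benchmark <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$grid, file.path(out_dir, "grid.tsv"))
  for (nm in names(res$frequencies)) {
    readr::write_tsv(res$frequencies[[nm]],
                     file.path(out_dir, paste0("frequency_", nm, ".tsv")))
  }
  sel_dir <- file.path(out_dir, "selections")
  dir.create(sel_dir, showWarnings = FALSE)
  for (key in names(res$selections)) {
    sel <- res$selections[[key]]
    jsonlite::write_json(
      list(methods = sel$methods, iterations = sel$iterations,
           stable_set = sel$stable_set, s0 = sel$s0, alpha = sel$alpha,
           k = sel$k, coefficient = sel$coefficient,
           m_pairs = sel$m_pairs),
      file.path(sel_dir, paste0(key, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(settings = res$settings,
                   config_hash = rlang::hash(res$settings),
                   n_methods = length(unique(res$grid$method)),
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
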