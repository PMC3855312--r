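#' Construct a feature tibble
#'
#' Common output contract of the input-data representations: a tibble with
#' a `sample_id` column followed by numeric feature columns and no missing
#' entries.
#'
#' @param values n_samples x n_features numeric matrix with rownames =
#'   sample ids and colnames = feature ids.
#' @param kind One of `"calls"`, `"logratio"`, `"smoothed"`, `"pca"`, `"mr"`.
#' @return A `cgh_features` tibble with attribute `kind`.
#' @export
cgh_features <- function(values, kind) {
  kind <- match.arg(kind, c("calls", "logratio", "smoothed", "pca", "mr"))
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (anyNA(values)) abort("feature matrix must not contain missing values")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  out <- as_tibble(as.data.frame(values, check.names = FALSE))
  out <- tibble(sample_id = rownames(values), !!!out)
  structure(out, kind = kind, class = c("cgh_features", class(as_tibble(out))))
}

#' @export
print.cgh_features <- function(x, ...) {
  cat("<cgh_features> kind:", attr(x, "kind"), "-", nrow(x), "samples x",
      ncol(x) - 1L, "features\n")
  NextMethod()
}

features_matrix <- function(x) {
  m <- as.matrix(as_tibble(x)[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  m
}

#' All-probes feature representation
#'
#' Pass-through representation that treats every probe as a feature:
#' used for the calls, logratio and smoothed-logratio strategies.
#'
#' @param x An imputed `cgh_profile`.
#' @return A `cgh_features` tibble (samples x probes).
#' @export
as_features <- function(x) {
  stopifnot(inherits(x, "cgh_profile"))
  m <- profile_matrix(x)
  if (anyNA(m)) abort("profile has missing values; run impute_missing() first")
  cgh_features(m, kind = profile_kind(x))
}

#' Statistical compression by principal components
#'
#' Reduces the probe dimension by PCA of the samples x probes matrix
#' (probes centered, not scaled: logratios share a scale). The number of
#' retained components is the smallest m whose cumulative explained-variance
#' fraction reaches `var_fraction`; the retained scores become the features.
#'
#' @param x An imputed logratio/smoothed `cgh_profile` (calls are accepted
#'   and treated as numeric), with at least two samples.
#' @param var_fraction Minimum cumulative fraction of variance to retain
#'   (default 0.90).
#' @return A `cgh_features` tibble of PC scores with attributes
#'   `explained_variance` (per retained component) and `n_components`.
#' @export
pca_compress <- function(x, var_fraction = 0.90) {
  stopifnot(var_fraction > 0, var_fraction <= 1)
  m <- if (inherits(x, "cgh_profile")) profile_matrix(x) else
    features_matrix(x)
  if (anyNA(m)) abort("input has missing values; impute first")
  if (nrow(m) < 2) abort("PCA needs at least 2 samples")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= 0) abort("zero total variance; PCA undefined")
  cum <- cumsum(ev) / total
  k <- which(cum >= var_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  k <- max(1L, k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  out <- cgh_features(scores, kind = "pca")
  attr(out, "explained_variance") <- ev[seq_len(k)] / total
  attr(out, "n_components") <- k
  out
}

#' Extract minimal regions of alteration
#'
#' A minimal region (MR) is the largest run of contiguous probes, within one
#' chromosome, over which a subset of samples (its support) all carry the
#' same non-normal call (-1 loss, 1 gain, 2 amplification). Formally, an
#' interval is reported when extending it by one probe on either side
#' strictly shrinks its support and no strictly larger interval has the
#' identical support. Only regions whose support size reaches
#' `ceiling(min_support_fraction * n_samples)` are kept.
#'
#' @param x An imputed calls `cgh_profile`.
#' @param min_support_fraction Support threshold as a fraction of the cohort
#'   size, in (0, 1].
#' @return A `cgh_mrset` tibble sorted by (chromosome, start, alteration)
#'   with columns `chromosome`, `start_idx`/`end_idx` (0-based half-open
#'   bounds on the global genome order index), `start_pos`/`end_pos` (bp of
#'   the first/last probe), `alteration`, `support` (list-column of sample
#'   ids) and `n_support`. Attributes: `min_support_fraction`, `n_samples`,
#'   `sample_ids`.
#' @export
extract_minimal_regions <- function(x, min_support_fraction) {
  stopifnot(inherits(x, "cgh_profile"), profile_kind(x) == "calls",
            min_support_fraction > 0, min_support_fraction <= 1)
  m <- profile_matrix(x)
  if (anyNA(m)) abort("profile has missing values; run impute_missing() first")
  samples <- rownames(m)
  n <- length(samples)
  min_support <- as.integer(ceiling(min_support_fraction * n))
  chrom <- x$chromosome
  pos <- x$position

  rows <- list()
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)         # contiguous block in genome order
    sub <- m[, cols, drop = FALSE]
    p <- length(cols)
    for (a in c(-1L, 1L, 2L)) {
      hit <- sub == a                  # n x p logical
      for (s in seq_len(p)) {
        cur <- which(hit[, s])
        if (length(cur) < min_support) next
        # skip starts whose left one-probe extension keeps support intact:
        # such intervals re-appear from an earlier start
        e <- s
        repeat {
          if (e == p) break
          nxt <- cur[hit[cur, e + 1L]]
          if (length(nxt) == length(cur)) {
            e <- e + 1L
          } else {
            # support would strictly shrink at e+1: [s, e] is right-maximal
            # for this support; emit, then continue with the shrunken support
            rows <- emit_region(rows, hit, ch, cols, pos, s, e, a, cur,
                                min_support)
            if (length(nxt) < min_support) break
            cur <- nxt
            e <- e + 1L
          }
        }
        if (e == p) {
          rows <- emit_region(rows, hit, ch, cols, pos, s, e, a, cur,
                              min_support)
        }
      }
    }
  }
  regions <- if (length(rows) == 0) {
    tibble(chromosome = character(), start_idx = integer(),
           end_idx = integer(), start_pos = numeric(), end_pos = numeric(),
           alteration = integer(), support = list(), n_support = integer())
  } else {
    dplyr::bind_rows(rows)
  }
  regions$support <- lapply(regions$support, function(i) samples[i])
  regions <- regions[order(chromosome_rank(regions$chromosome),
                           regions$start_idx, regions$alteration), ,
                     drop = FALSE]
  structure(as_tibble(regions),
            min_support_fraction = min_support_fraction,
            n_samples = n, sample_ids = samples,
            class = c("cgh_mrset", class(as_tibble(regions))))
}

# keep [s, e] iff the left one-probe extension strictly shrinks the support
emit_region <- function(rows, hit, ch, cols, pos, s, e, a, cur, min_support) {
  if (length(cur) < min_support) return(rows)
  if (s > 1L && all(hit[cur, s - 1L])) return(rows)
  rows[[length(rows) + 1L]] <- tibble(
    chromosome = ch,
    start_idx = cols[s] - 1L, end_idx = cols[e],
    start_pos = pos[cols[s]], end_pos = pos[cols[e]],
    alteration = a, support = list(cur), n_support = length(cur))
  rows
}

#' @export
print.cgh_mrset <- function(x, ...) {
  cat("<cgh_mrset>", nrow(x), "minimal regions;",
      "support fraction >=", attr(x, "min_support_fraction"),
      "of", attr(x, "n_samples"), "samples\n")
  NextMethod()
}

#' Binary minimal-region membership features
#'
#' The biological-compression representation: one binary feature per
#' minimal region, coded 1 when the sample belongs to the region's support.
#'
#' @param mrs A `cgh_mrset` from [extract_minimal_regions()].
#' @param sample_ids Optional sample ordering; defaults to the cohort the
#'   regions were extracted from.
#' @return A `cgh_features` tibble with kind `"mr"`; feature names encode
#'   chromosome, probe interval and alteration.
#' @export
mr_membership_matrix <- function(mrs, sample_ids = attr(mrs, "sample_ids")) {
  stopifnot(inherits(mrs, "cgh_mrset"))
  if (nrow(mrs) == 0) {
    abort("empty minimal-region set; lower min_support_fraction")
  }
  alt_code <- c(`-1` = "loss", `1` = "gain", `2` = "amp")
  feat <- sprintf("%s:%d-%d:%s", mrs$chromosome, mrs$start_idx, mrs$end_idx,
                  alt_code[as.character(mrs$alteration)])
  m <- matrix(0L, nrow = length(sample_ids), ncol = nrow(mrs),
              dimnames = list(sample_ids, feat))
  for (r in seq_len(nrow(mrs))) {
    m[intersect(mrs$support[[r]], sample_ids), r] <- 1L
  }
  cgh_features(m, kind = "mr")
}

#' Export minimal regions as BED-like TSV
#'
#' Writes one row per region: chromosome, start/end probe positions (bp),
#' alteration, support size and comma-separated support sample list.
#'
#' @param mrs A `cgh_mrset`.
#' @param path Output path.
#' @export
write_mrset_bed <- function(mrs, path) {
  stopifnot(inherits(mrs, "cgh_mrset"))
  df <- data.frame(chrom = mrs$chromosome, start = mrs$start_pos,
                   end = mrs$end_pos, alteration = mrs$alteration,
                   n_support = mrs$n_support,
                   support = vapply(mrs$support, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
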