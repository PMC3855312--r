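new_pairwise_matrix <- function(values, measure, class) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-9) abort("matrix is not symmetric")
  values <- (values + t(values)) / 2
  structure(values, measure = measure, class = c(class, "matrix", "array"))
}

#' Similarity and dissimilarity matrices
#'
#' Classed symmetric sample x sample matrices. Similarities carry no
#' constraint beyond symmetry; dissimilarities are non-negative with a zero
#' diagonal. `tidy()` turns either into a long tibble of pairs.
#'
#' @param values Symmetric numeric matrix with sample ids as dimnames.
#' @param measure Name of the measure that produced it.
#' @return A `cgh_similarity` / `cgh_dissimilarity` matrix.
#' @export
similarity_matrix <- function(values, measure = "similarity") {
  new_pairwise_matrix(values, measure, "cgh_similarity")
}

#' @rdname similarity_matrix
#' @export
dissimilarity_matrix <- function(values, measure = "dissimilarity") {
  if (any(values < -1e-12)) abort("dissimilarities must be non-negative")
  diag(values) <- 0
  new_pairwise_matrix(pmax(values, 0), measure, "cgh_dissimilarity")
}

#' @export
tidy.cgh_similarity <- function(x, ...) pairwise_tidy(x)

#' @export
tidy.cgh_dissimilarity <- function(x, ...) pairwise_tidy(x)

pairwise_tidy <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
         value = x[idx], measure = attr(x, "measure"))
}

#' Vector dissimilarities between samples
#'
#' Standard row-wise dissimilarities on any feature representation:
#' Euclidean (L2), Manhattan (L1), or Pearson dissimilarity 1 - r
#' (range \[0, 2\]).
#'
#' @param x A `cgh_features` tibble (or imputed `cgh_profile`).
#' @param metric One of `"euclidean"`, `"manhattan"`, `"pearson"`.
#' @return A `cgh_dissimilarity` matrix.
#' @export
vector_dissimilarity <- function(x, metric = c("euclidean", "manhattan",
                                               "pearson")) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "cgh_profile")) profile_matrix(x) else
    features_matrix(x)
  if (anyNA(m)) abort("missing values; impute first")
  d <- if (metric == "pearson") {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      abort(paste0("zero-variance sample(s) under pearson: ",
                   paste(rownames(m)[sds == 0], collapse = ", ")))
    }
    1 - stats::cor(t(m))
  } else {
    as.matrix(stats::dist(m, method = metric))
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  dissimilarity_matrix(d, measure = metric)
}

# maximal runs of constant non-zero call, per sample per chromosome,
# on the global 0-based genome order index (half-open intervals)
call_segments <- function(x) {
  stopifnot(inherits(x, "cgh_profile"), profile_kind(x) == "calls")
  m <- profile_matrix(x)
  if (anyNA(m)) abort("missing values; impute first")
  chrom <- x$chromosome
  out <- vector("list", nrow(m))
  names(out) <- rownames(m)
  for (i in seq_len(nrow(m))) {
    segs <- list()
    for (ch in unique(chrom)) {
      cols <- which(chrom == ch)
      v <- m[i, cols]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0
      if (any(keep)) {
        segs[[length(segs) + 1L]] <- data.frame(
          start = cols[starts[keep]] - 1L,
          end = cols[ends[keep]],
          value = r$values[keep])
      }
    }
    out[[i]] <- if (length(segs)) do.call(rbind, segs) else
      data.frame(start = integer(), end = integer(), value = integer())
  }
  out
}

#' Segment-overlap similarity (sim)
#'
#' Counts the contiguous altered intervals of the same type that overlap
#' between two profiles. On calls, each sample is decomposed per chromosome
#' into maximal runs of a constant non-normal call; `sim(x, y)` is the
#' number of (segment of x, segment of y) pairs with identical alteration
#' and overlapping probe intervals (gain and amplification are distinct
#' types). On a binary minimal-region representation, `sim(x, y)` is the
#' number of regions whose support contains both samples. The raw diagonal
#' is the sample's own segment (or region-membership) count, which can be
#' exceeded off-diagonal; see [correct_sim_diagonal()].
#'
#' @param x A calls `cgh_profile`, or a `cgh_features` tibble of kind
#'   `"mr"`.
#' @return An integer-valued `cgh_similarity` matrix.
#' @export
sim_similarity <- function(x) {
  if (inherits(x, "cgh_features")) {
    if (attr(x, "kind") != "mr") {
      abort("sim on features requires the binary minimal-region kind")
    }
    b <- features_matrix(x)
    s <- b %*% t(b)
    return(similarity_matrix(s, measure = "sim"))
  }
  segs <- call_segments(x)
  n <- length(segs)
  s <- matrix(0, n, n, dimnames = list(names(segs), names(segs)))
  for (i in seq_len(n)) {
    a <- segs[[i]]
    for (j in i:n) {
      b <- segs[[j]]
      if (nrow(a) == 0 || nrow(b) == 0) next
      cnt <- 0L
      for (v in unique(a$value)) {
        ai <- a[a$value == v, , drop = FALSE]
        bi <- b[b$value == v, , drop = FALSE]
        if (nrow(bi) == 0) next
        # overlap of half-open intervals
        cnt <- cnt + sum(outer(ai$start, bi$end, `<`) &
                           outer(ai$end, bi$start, `>`))
      }
      s[i, j] <- s[j, i] <- cnt
    }
  }
  similarity_matrix(s, measure = "sim")
}

#' Correct the sim diagonal
#'
#' Raw `sim` self-similarity can be smaller than the similarity to another
#' sample (a single long segment of x can overlap several segments of y).
#' The correction replaces each diagonal entry by its row maximum so that
#' every sample is at least as similar to itself as to any other sample;
#' off-diagonal entries are unchanged.
#'
#' @param s A `cgh_similarity` from [sim_similarity()].
#' @return The corrected `cgh_similarity`.
#' @export
correct_sim_diagonal <- function(s) {
  stopifnot(inherits(s, "cgh_similarity"))
  out <- unclass(s)
  diag(out) <- pmax(diag(out), apply(out, 1, max))
  similarity_matrix(out, measure = paste0(attr(s, "measure"), "_corrected"))
}

#' Agreement similarity (agree)
#'
#' Probability that the calls of two samples are identical at a uniformly
#' random probe: the fraction of probes (or binary region features) with
#' equal values. Values in \[0, 1\], unit diagonal. Invariant to probe
#' permutations.
#'
#' @param x An imputed calls `cgh_profile` or a binary `cgh_features` of
#'   kind `"mr"`.
#' @return A `cgh_similarity` matrix.
#' @export
agree_similarity <- function(x) {
  m <- dissim_input_matrix(x)
  p <- ncol(m)
  vals <- sort(unique(as.vector(m)))
  s <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (v in vals) {
    ind <- (m == v) * 1
    s <- s + ind %*% t(ind)
  }
  similarity_matrix(s / p, measure = "agree")
}

#' Concordance similarity (conc)
#'
#' Probability that two samples order a uniformly random pair of probes the
#' same way: the fraction, over all unordered probe pairs \{p, q\}, of pairs
#' with sign(x_p - x_q) = sign(y_p - y_q) (sign in \{-, 0, +\}). Values in
#' \[0, 1\], unit diagonal. Computed from the joint call-category counts in
#' O(levels^2) per sample pair rather than by scanning all probe pairs.
#'
#' @param x An imputed calls `cgh_profile` (at least 2 probes) or a binary
#'   `cgh_features` of kind `"mr"`.
#' @return A `cgh_similarity` matrix.
#' @export
conc_similarity <- function(x) {
  m <- dissim_input_matrix(x)
  p <- ncol(m)
  if (p < 2) abort("conc needs at least 2 probes")
  n <- nrow(m)
  vals <- sort(unique(as.vector(m)))
  L <- length(vals)
  ind <- lapply(vals, function(v) (m == v) * 1)   # per-level indicators
  # joint counts N[a,b](x,y) = #probes with x=vals[a], y=vals[b]
  joint <- vector("list", L * L)
  for (a in seq_len(L)) for (b in seq_len(L)) {
    joint[[(a - 1) * L + b]] <- ind[[a]] %*% t(ind[[b]])
  }
  npairs <- p * (p - 1) / 2
  conc <- matrix(0, n, n)
  for (a in seq_len(L)) for (b in seq_len(L)) {
    Nab <- joint[[(a - 1) * L + b]]
    # pairs within one joint category are always concordant (both signs 0)
    conc <- conc + Nab * (Nab - 1) / 2
    for (cc in seq_len(L)) for (d in seq_len(L)) {
      i1 <- (a - 1) * L + b
      i2 <- (cc - 1) * L + d
      if (i2 <= i1) next
      if (sign(vals[a] - vals[cc]) == sign(vals[b] - vals[d])) {
        conc <- conc + Nab * joint[[i2]]
      }
    }
  }
  dimnames(conc) <- list(rownames(m), rownames(m))
  similarity_matrix(conc / npairs, measure = "conc")
}

dissim_input_matrix <- function(x) {
  if (inherits(x, "cgh_features")) {
    if (!attr(x, "kind") %in% c("mr", "calls")) {
      abort("agree/conc require calls or binary minimal-region input")
    }
    return(features_matrix(x))
  }
  stopifnot(inherits(x, "cgh_profile"))
  if (profile_kind(x) != "calls") {
    abort("agree/conc are defined on calls (or minimal regions) only")
  }
  m <- profile_matrix(x)
  if (anyNA(m)) abort("missing values; impute first")
  m
}

#' Convert a similarity to a dissimilarity
#'
#' Each off-diagonal similarity is subtracted from the maximum value of the
#' matrix; the diagonal is forced to zero.
#'
#' @param s A `cgh_similarity` (for `sim`, the diagonal-corrected one).
#' @return A non-negative `cgh_dissimilarity` matrix.
#' @export
similarity_to_dissimilarity <- function(s) {
  stopifnot(inherits(s, "cgh_similarity"))
  d <- max(s) - unclass(s)
  diag(d) <- 0
  dissimilarity_matrix(d, measure = paste0("max_minus_",
                                           attr(s, "measure")))
}
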