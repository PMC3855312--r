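# fixtures and independent brute-force oracles used across the suite

# calls profile from a samples x probes matrix (one chromosome by default)
mk_calls <- function(m, chrom = NULL, positions = NULL) {
  p <- ncol(m)
  df <- data.frame(
    probe_id = paste0("p", seq_len(p)),
    chromosome = if (is.null(chrom)) rep("1", p) else chrom,
    position = if (is.null(positions)) seq_len(p) * 100 else positions)
  for (i in seq_len(nrow(m))) df[[paste0("s", i)]] <- m[i, ]
  cgh_profile(df, "calls")
}

mk_logratio <- function(m, chrom = NULL, positions = NULL) {
  p <- ncol(m)
  df <- data.frame(
    probe_id = paste0("p", seq_len(p)),
    chromosome = if (is.null(chrom)) rep("1", p) else chrom,
    position = if (is.null(positions)) seq_len(p) * 100 else positions)
  for (i in seq_len(nrow(m))) df[[paste0("s", i)]] <- m[i, ]
  cgh_profile(df, "logratio")
}

random_call_matrix <- function(n, p, seed) {
  withr::with_seed(seed, {
    matrix(sample(c(-1L, 0L, 1L, 2L), n * p, replace = TRUE), n, p)
  })
}

# oracle: enumerate every within-chromosome interval x alteration, keep
# intervals with support >= threshold that are not strictly contained in a
# larger interval with identical support
oracle_minimal_regions <- function(m, chrom, fraction) {
  n <- nrow(m)
  thr <- ceiling(fraction * n)
  out <- list()
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    for (a in c(-1L, 1L, 2L)) {
      iv <- list()
      for (s in seq_along(cols)) {
        for (e in s:length(cols)) {
          block <- m[, cols[s:e], drop = FALSE] == a
          supp <- which(rowSums(block) == (e - s + 1))
          iv[[length(iv) + 1L]] <- list(s = s, e = e, supp = supp)
        }
      }
      for (v in iv) {
        if (length(v$supp) < thr) next
        contained <- any(vapply(iv, function(w) {
          (w$e - w$s > v$e - v$s) && w$s <= v$s && w$e >= v$e &&
            identical(w$supp, v$supp)
        }, logical(1)))
        if (!contained) {
          out[[length(out) + 1L]] <- data.frame(
            chromosome = ch, start_idx = cols[v$s] - 1L,
            end_idx = cols[v$e], alteration = a,
            support = paste(v$supp, collapse = ","))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chromosome = character(), start_idx = integer(),
                      end_idx = integer(), alteration = integer(),
                      support = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$start_idx, res$alteration), , drop = FALSE]
}

mrset_as_oracle_frame <- function(mrs) {
  ids <- attr(mrs, "sample_ids")
  data.frame(chromosome = mrs$chromosome, start_idx = mrs$start_idx,
             end_idx = mrs$end_idx, alteration = mrs$alteration,
             support = vapply(mrs$support, function(s) {
               paste(sort(match(s, ids)), collapse = ",")
             }, character(1)))
}

# oracle: sim by explicit enumeration of all pairs of constant non-zero runs
oracle_sim_pair <- function(x, y, chrom) {
  runs <- function(v) {
    segs <- list()
    for (ch in unique(chrom)) {
      cols <- which(chrom == ch)
      r <- rle(v[cols])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in seq_along(r$values)) {
        if (r$values[i] != 0) {
          segs[[length(segs) + 1L]] <- c(cols[starts[i]], cols[ends[i]],
                                         r$values[i])
        }
      }
    }
    segs
  }
  rx <- runs(x)
  ry <- runs(y)
  cnt <- 0L
  for (a in rx) {
    for (b in ry) {
      if (a[3] == b[3] && a[1] <= b[2] && b[1] <= a[2]) cnt <- cnt + 1L
    }
  }
  cnt
}

# oracle: conc by a full O(P^2) probe-pair scan
oracle_conc_pair <- function(x, y) {
  p <- length(x)
  conc <- 0L
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (sign(x[i] - x[j]) == sign(y[i] - y[j])) conc <- conc + 1L
    }
  }
  conc / (p * (p - 1) / 2)
}

# exhaustive k = 2 medoid optimum for the k-centroids property
oracle_best_medoid_pair <- function(d) {
  n <- nrow(d)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      obj <- sum(pmin(d[, i], d[, j]))
      if (obj < best) best <- obj
    }
  }
  best
}

# simulated stability record with given per-pair similarities
make_record <- function(label, sims, k = 3L, coefficient = "jaccard") {
  m <- method_spec("calls", "euclidean", "ward")
  m$label <- label
  structure(list(method = m, k = as.integer(k), coefficient = coefficient,
                 similarities = sims, mean = mean(sims),
                 m_pairs = length(sims), rate = 0.8,
                 failures = character(0)),
            class = "stability_record")
}

# are two partitions identical up to relabeling?
same_partition <- function(p, q) {
  p <- p[sort(names(p))]
  q <- q[sort(names(q))]
  length(p) == length(q) &&
    isTRUE(all.equal(partition_agreement(p, q, "simple_matching"), 1))
}
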