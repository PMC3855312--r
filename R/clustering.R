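#' Agglomerative hierarchical clustering
#'
#' Standard Lance-Williams agglomeration of a dissimilarity matrix with
#' complete, average (UPGMA), weighted (WPGMA) or Ward linkage (ward.D2
#' convention: Ward update on squared dissimilarities).
#'
#' @param d A `cgh_dissimilarity` matrix (n >= 2).
#' @param linkage One of `"complete"`, `"average"`, `"weighted"`, `"ward"`.
#' @return An `hclust` dendrogram with the sample ids as labels.
#' @export
agglomerative_cluster <- function(d, linkage = c("complete", "average",
                                                 "weighted", "ward")) {
  linkage <- match.arg(linkage)
  d <- check_dissimilarity(d)
  method <- switch(linkage, complete = "complete", average = "average",
                   weighted = "mcquitty", ward = "ward.D2")
  stats::hclust(stats::as.dist(d), method = method)
}

check_dissimilarity <- function(d) {
  if (inherits(d, "cgh_dissimilarity")) return(unclass(d))
  if (!is.matrix(d) || nrow(d) != ncol(d) ||
        max(abs(d - t(d))) > 1e-9) {
    abort("expected a symmetric dissimilarity matrix")
  }
  if (nrow(d) < 2) abort("need at least 2 samples")
  unclass(d)
}

#' Divisive hierarchical clustering (diana)
#'
#' Classic divisive analysis: at each step the cluster with the largest
#' diameter is split by seeding a splinter group with the most dissimilar
#' object and iteratively moving objects closer to the splinter.
#'
#' @param d A `cgh_dissimilarity` matrix (n >= 2).
#' @return An `hclust` dendrogram (converted from the divisive banner) whose
#'   cuts reproduce the successive splits.
#' @export
diana_cluster <- function(d) {
  d <- check_dissimilarity(d)
  dv <- cluster::diana(stats::as.dist(d), diss = TRUE)
  stats::as.hclust(dv)
}

#' Cut a dendrogram into a flat partition
#'
#' @param tree An `hclust` dendrogram.
#' @param k Number of clusters, 1 <= k <= n.
#' @return A `cgh_partition`: named integer vector mapping sample id to a
#'   cluster label in 1..k.
#' @export
cut_dendrogram <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1 || k > n) abort("k out of range")
  as_partition(stats::cutree(tree, k = k))
}

as_partition <- function(labels) {
  stats::setNames(as.integer(factor(labels, levels = unique(labels))),
                  names(labels))
}

#' k-means partition of a feature representation
#'
#' Lloyd's algorithm on the Euclidean geometry of a feature matrix, best of
#' `restarts` seeded random initialisations by within-cluster sum of
#' squares. When fewer than `k` distinct rows exist the distinct rows seed
#' the clusters and duplicates follow their row.
#'
#' @param x A `cgh_features` tibble (or numeric matrix with rownames).
#' @param k Number of clusters (k <= n).
#' @param seed Integer seed making the restarts reproducible.
#' @param restarts Number of random initialisations (default 10).
#' @return A `cgh_partition` with attribute `wcss`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, restarts = 10L) {
  m <- if (is.matrix(x)) x else features_matrix(x)
  n <- nrow(m)
  if (k > n) abort("k exceeds the number of samples")
  if (k == n) {
    p <- as_partition(stats::setNames(seq_len(n), rownames(m)))
    attr(p, "wcss") <- 0
    return(p)
  }
  distinct <- !duplicated(m)
  if (sum(distinct) <= k) {
    # fewer distinct rows than clusters: distinct rows seed the clusters,
    # surplus duplicates are promoted to singleton clusters (WCSS stays 0
    # for the promoted rows since their center coincides)
    labels <- match(apply(m, 1, paste, collapse = "\r"),
                    apply(m[distinct, , drop = FALSE], 1, paste,
                          collapse = "\r"))
    extra <- k - max(labels)
    if (extra > 0) {
      dup_rows <- which(!distinct)[seq_len(extra)]
      labels[dup_rows] <- max(labels) + seq_len(extra)
    }
    p <- as_partition(stats::setNames(labels, rownames(m)))
    centers <- rowsum(m, labels) / as.vector(table(labels))
    attr(p, "wcss") <- sum((m - centers[labels, , drop = FALSE])^2)
    return(p)
  }
  fit <- withr::with_seed(seed, {
    {
      best <- NULL
      for (r in seq_len(restarts)) {
        f <- tryCatch(
          suppressWarnings(stats::kmeans(m, centers = k,
                                         algorithm = "Lloyd",
                                         iter.max = 50)),
          error = function(e) NULL)
        if (!is.null(f) && (is.null(best) ||
                              f$tot.withinss < best$tot.withinss)) best <- f
      }
      if (is.null(best)) abort("k-means failed on degenerate input")
      best
    }
  })
  p <- as_partition(stats::setNames(fit$cluster, rownames(m)))
  attr(p, "wcss") <- fit$tot.withinss
  p
}

#' k-centroids (k-medoids) partition of a dissimilarity matrix
#'
#' Adapts k-means to an arbitrary dissimilarity: each cluster is represented
#' by the object (medoid) with minimal average dissimilarity to the cluster,
#' and assignment/update steps alternate to a fixed point, followed by a
#' greedy medoid-swap refinement. Best of `restarts` seeded random medoid
#' initialisations by the total dissimilarity of objects to their medoid.
#'
#' @param d A `cgh_dissimilarity` matrix.
#' @param k Number of clusters (k <= n).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @return A `cgh_partition` with attributes `medoids` and `objective`.
#' @export
kcentroids_cluster <- function(d, k, seed = 1L, restarts = 10L) {
  d <- check_dissimilarity(d)
  n <- nrow(d)
  if (k > n) abort("k exceeds the number of samples")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  best <- NULL
  starts <- withr::with_seed(seed, {
    lapply(seq_len(restarts), function(r) sample.int(n, k))
  })
  for (med in starts) {
    res <- kcentroids_run(d, med)
    if (is.null(best) || res$objective < best$objective - 1e-12) best <- res
  }
  p <- as_partition(stats::setNames(best$labels, ids))
  attr(p, "medoids") <- ids[best$medoids]
  attr(p, "objective") <- best$objective
  p
}

kcentroids_run <- function(d, medoids) {
  n <- nrow(d)
  for (iter in seq_len(100L)) {
    # assignment: nearest medoid, ties to the lower medoid index
    assign <- apply(d[, medoids, drop = FALSE], 1, which.min)
    assign[medoids] <- seq_along(medoids)  # medoids stay in their cluster
    # empty-cluster repair: move in the object farthest from its medoid
    for (c in seq_along(medoids)) {
      if (!any(assign == c)) {
        far <- which.max(d[cbind(seq_len(n), medoids[assign])])
        assign[far] <- c
        medoids[c] <- far
      }
    }
    new_medoids <- vapply(seq_along(medoids), function(c) {
      members <- which(assign == c)
      members[which.min(colMeans(d[members, members, drop = FALSE]))]
    }, integer(1))
    if (identical(sort(new_medoids), sort(medoids)) || iter == 100L) {
      return(kcentroids_swap(d, new_medoids))
    }
    medoids <- new_medoids
  }
}

# greedy swap refinement: replace one medoid by a non-medoid whenever that
# lowers the total dissimilarity to the nearest medoid; escapes the local
# optima the alternating scheme can converge to
kcentroids_swap <- function(d, medoids) {
  n <- nrow(d)
  obj <- function(meds) sum(apply(d[, meds, drop = FALSE], 1, min))
  best <- obj(medoids)
  repeat {
    improved <- FALSE
    for (c in seq_along(medoids)) {
      for (o in setdiff(seq_len(n), medoids)) {
        cand <- medoids
        cand[c] <- o
        val <- obj(cand)
        if (val < best - 1e-12) {
          medoids <- cand
          best <- val
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  assign <- apply(d[, medoids, drop = FALSE], 1, which.min)
  assign[medoids] <- seq_along(medoids)
  list(labels = assign, medoids = medoids, objective = best)
}

#' Total-linkage clustering of called profiles
#'
#' Agglomerative scheme for called copy-number data associated with the
#' agree and conc similarities: at each step the pair of clusters whose
#' merger is tightest is merged, where the tightness of a cluster is the
#' minimum pairwise similarity among its members. Tight clusters are
#' favoured throughout; merging stops at `k` clusters. Ties are broken by
#' the smallest cluster index pair, so the procedure is deterministic.
#'
#' @param x An imputed calls `cgh_profile`, a binary `cgh_features` of kind
#'   `"mr"`, or a precomputed agree/conc `cgh_similarity`.
#' @param measure `"agree"` or `"conc"` (ignored when `x` is already a
#'   similarity matrix).
#' @param k Number of clusters.
#' @return A `cgh_partition`.
#' @export
total_cluster <- function(x, measure = c("agree", "conc"), k) {
  if (inherits(x, "cgh_similarity")) {
    s <- x
  } else {
    measure <- match.arg(measure)
    s <- if (measure == "agree") agree_similarity(x) else conc_similarity(x)
  }
  s <- unclass(s)
  n <- nrow(s)
  if (k < 1 || k > n) abort("k out of range")
  ids <- rownames(s)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  clusters <- as.list(seq_len(n))
  tight <- rep(Inf, n)                 # singleton tightness is vacuous
  cross <- s                           # min cross-similarity between clusters
  diag(cross) <- NA
  while (length(clusters) > k) {
    nc <- length(clusters)
    # tightness of each candidate merger, ties to the smallest (i, j) pair
    merged <- pmin(outer(tight[seq_len(nc)], tight[seq_len(nc)], pmin),
                   cross[seq_len(nc), seq_len(nc)])
    merged[lower.tri(merged, diag = TRUE)] <- -Inf
    best <- which(merged == max(merged, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    tight[i] <- merged[i, j]
    cross[i, ] <- pmin(cross[i, ], cross[j, ])
    cross[, i] <- cross[i, ]
    diag(cross) <- NA
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    tight <- tight[-j]
    cross <- cross[-j, -j, drop = FALSE]
  }
  labels <- integer(n)
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  as_partition(stats::setNames(labels, ids))
}

#' Tidy a partition
#'
#' @param x A `cgh_partition` (named integer vector).
#' @param ... Unused.
#' @return A tibble with columns `sample_id` and `cluster`.
#' @export
partition_tidy <- function(x, ...) {
  tibble(sample_id = names(x), cluster = as.integer(x))
}

#' Write a partition as two-column TSV
#'
#' @param x A `cgh_partition`.
#' @param path Output path.
#' @export
write_partition <- function(x, path) {
  utils::write.table(partition_tidy(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
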