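four_point_d <- function() {
  d <- matrix(10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 2
  diag(d) <- 0
  dissimilarity_matrix(d)
}

test_that("average linkage merges the hand-computed hierarchy", {
  tree <- agglomerative_cluster(four_point_d(), "average")
  expect_equal(tree$height, c(1, 2, 10))
  p <- cut_dendrogram(tree, 2)
  expect_true(same_partition(p, c(a = 1, b = 1, c = 2, d = 2)))
  expect_equal(length(unique(cut_dendrogram(tree, 4))), 4)
  expect_equal(length(unique(cut_dendrogram(tree, 1))), 1)
  expect_error(cut_dendrogram(tree, 5), "out of range")
})

test_that("two points merge at their distance; duplicates merge at zero", {
  d2 <- dissimilarity_matrix(matrix(c(0, 3, 3, 0), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  tree <- agglomerative_cluster(d2, "complete")
  expect_equal(tree$height, 3)

  d3 <- matrix(5, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d3["a", "b"] <- d3["b", "a"] <- 0
  diag(d3) <- 0
  tree3 <- agglomerative_cluster(dissimilarity_matrix(d3), "average")
  expect_equal(tree3$height[1], 0)
  expect_true(same_partition(cut_dendrogram(tree3, 2),
                             c(a = 1, b = 1, c = 2)))
})

test_that("diana splits the widest cluster first", {
  tree <- diana_cluster(four_point_d())
  expect_true(same_partition(cut_dendrogram(tree, 2),
                             c(a = 1, b = 1, c = 2, d = 2)))
  d2 <- dissimilarity_matrix(matrix(c(0, 3, 3, 0), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  expect_equal(length(unique(cut_dendrogram(diana_cluster(d2), 2))), 2)
})

test_that("agglomerative heights are monotone for the monotone linkages", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(3:10, 1))
    m <- withr::with_seed(seed + 1, matrix(runif(n * n), n))
    d <- dissimilarity_matrix((m + t(m)) / 2 * (1 - diag(n)))
    for (linkage in c("complete", "average", "weighted")) {
      h <- agglomerative_cluster(d, linkage)$height
      expect_true(all(diff(h) >= -1e-12),
                  info = paste(linkage, "seed", seed))
    }
  }
})

test_that("kmeans separates well-separated 1-D groups", {
  f <- cgh_features(matrix(c(0, 0.1, 10, 10.1), 4, 1,
                           dimnames = list(paste0("s", 1:4), "x")),
                    kind = "pca")
  p <- kmeans_cluster(f, 2, seed = 11)
  expect_true(same_partition(p, c(s1 = 1, s2 = 1, s3 = 2, s4 = 2)))
  expect_equal(attr(p, "wcss"), 0.01, tolerance = 1e-9)

  pk <- kmeans_cluster(f, 4, seed = 11)
  expect_equal(attr(pk, "wcss"), 0)
  expect_equal(length(unique(pk)), 4)

  same <- cgh_features(matrix(1, 3, 2,
                              dimnames = list(paste0("s", 1:3), NULL)),
                       kind = "pca")
  ps <- kmeans_cluster(same, 2, seed = 11)
  expect_equal(attr(ps, "wcss"), 0)
  expect_equal(length(unique(ps)), 2)
})

test_that("kcentroids recovers the exhaustive medoid optimum", {
  p <- kcentroids_cluster(four_point_d(), 2, seed = 3)
  expect_true(same_partition(p, c(a = 1, b = 1, c = 2, d = 2)))
  expect_equal(attr(p, "objective"), oracle_best_medoid_pair(four_point_d()))

  pn <- kcentroids_cluster(four_point_d(), 4, seed = 3)
  expect_equal(attr(pn, "objective"), 0)
  expect_equal(length(unique(pn)), 4)

  const <- dissimilarity_matrix(matrix(1, 3, 3) - diag(3))
  pc1 <- kcentroids_cluster(const, 2, seed = 5)
  pc2 <- kcentroids_cluster(const, 2, seed = 5)
  expect_identical(pc1, pc2)
})

test_that("kcentroids best-of-restarts is near-exhaustive at k = 2", {
  hits <- 0
  for (seed in 1:100) {
    n <- withr::with_seed(seed + 200, sample(4:7, 1))
    m <- withr::with_seed(seed + 300, matrix(runif(n * n), n))
    d <- dissimilarity_matrix((m + t(m)) / 2 * (1 - diag(n)))
    p <- kcentroids_cluster(d, 2, seed = seed)
    if (abs(attr(p, "objective") - oracle_best_medoid_pair(unclass(d)))
        < 1e-9) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 95)
})

test_that("total linkage merges the tightest clusters first", {
  s <- similarity_matrix(matrix(c(1, 0.9, 0.5,
                                  0.9, 1, 0.5,
                                  0.5, 0.5, 1), 3,
                                dimnames = list(paste0("s", 1:3),
                                                paste0("s", 1:3))), "agree")
  p <- total_cluster(s, k = 2)
  expect_true(same_partition(p, c(s1 = 1, s2 = 1, s3 = 2)))

  prof2 <- mk_calls(rbind(c(1L, 0L), c(0L, 1L)))
  expect_equal(length(unique(total_cluster(prof2, "agree", k = 2))), 2)

  # duplicated rows form perfectly tight groups recovered at k = 2
  m <- rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L),
             c(0L, -1L, -1L, 1L), c(0L, -1L, -1L, 1L))
  p2 <- total_cluster(mk_calls(m), "agree", k = 2)
  expect_true(same_partition(p2, c(s1 = 1, s2 = 1, s3 = 2, s4 = 2)))
  p3 <- total_cluster(mk_calls(m), "conc", k = 2)
  expect_true(same_partition(p3, c(s1 = 1, s2 = 1, s3 = 2, s4 = 2)))
})

test_that("every partition has exactly k nonempty clusters", {
  for (seed in 1:30) {
    n <- withr::with_seed(seed + 400, sample(4:9, 1))
    m <- withr::with_seed(seed + 500, matrix(runif(n * n), n))
    d <- dissimilarity_matrix((m + t(m)) / 2 * (1 - diag(n)))
    k <- withr::with_seed(seed + 600, sample(2:(n - 1), 1))
    for (p in list(cut_dendrogram(agglomerative_cluster(d, "ward"), k),
                   cut_dendrogram(diana_cluster(d), k),
                   kcentroids_cluster(d, k, seed = seed))) {
      expect_equal(sort(unique(p)), seq_len(k))
      expect_true(all(tabulate(p, k) >= 1))
    }
  }
})
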