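test_that("vector dissimilarities reproduce closed-form values", {
  f <- cgh_features(rbind(a = c(0, 0), b = c(3, 4)), kind = "logratio")
  expect_equal(unname(vector_dissimilarity(f, "euclidean")["a", "b"]), 5)
  expect_equal(unname(vector_dissimilarity(f, "manhattan")["a", "b"]), 7)

  g <- cgh_features(rbind(a = c(1, 2, 3), b = c(1, 2, 3)), kind = "logratio")
  for (metric in c("euclidean", "manhattan", "pearson")) {
    expect_equal(unname(vector_dissimilarity(g, metric)["a", "b"]), 0)
  }

  h <- cgh_features(rbind(a = c(1, 2, 3), b = c(3, 2, 1)), kind = "logratio")
  expect_equal(unname(vector_dissimilarity(h, "pearson")["a", "b"]), 2)

  flat <- cgh_features(rbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                       kind = "logratio")
  expect_error(vector_dissimilarity(flat, "pearson"), "zero-variance.*a")
})

test_that("sim counts overlapping same-type segments", {
  prof <- mk_calls(rbind(c(1L, 1L, 0L, -1L, -1L),
                         c(0L, 1L, 1L, -1L, 0L)))
  s <- sim_similarity(prof)
  expect_equal(unname(s["s1", "s2"]), 2)

  # pathology: a single long run of x overlaps both runs of y
  prof2 <- mk_calls(rbind(c(1L, 1L, 1L, 1L), c(1L, 0L, 1L, 0L)))
  s2 <- sim_similarity(prof2)
  expect_equal(unname(s2["s1", "s2"]), 2)
  expect_equal(unname(s2["s1", "s1"]), 1)
  expect_equal(unname(s2["s2", "s2"]), 2)
  fixed <- correct_sim_diagonal(s2)
  expect_equal(unname(diag(fixed)), c(2, 2))
  expect_equal(fixed["s1", "s2"], s2["s1", "s2"])

  zero <- sim_similarity(mk_calls(matrix(0L, 2, 4)))
  expect_true(all(zero == 0))
  expect_identical(unclass(correct_sim_diagonal(zero))[, ],
                   unclass(zero)[, ])
})

test_that("sim matches the segment-pair oracle; runs stop at chromosomes", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(2:6, 1))
    p <- withr::with_seed(seed + 1, sample(4:15, 1))
    m <- random_call_matrix(n, p, seed + 2)
    chrom <- sort(withr::with_seed(seed + 3,
                                   sample(c("1", "2"), p, replace = TRUE)))
    s <- sim_similarity(mk_calls(m, chrom = chrom))
    for (i in seq_len(n)) {
      for (j in i:n) {
        expect_equal(unname(s[i, j]),
                     oracle_sim_pair(m[i, ], m[j, ], chrom),
                     info = sprintf("seed %d pair (%d,%d)", seed, i, j))
      }
    }
  }
})

test_that("after diagonal correction every diagonal entry is a row max", {
  for (seed in 1:30) {
    m <- random_call_matrix(5, 12, seed + 40)
    s <- correct_sim_diagonal(sim_similarity(mk_calls(m)))
    expect_true(all(diag(s) >= apply(s, 1, max) - 1e-12))
  }
})

test_that("agree is the fraction of identical calls", {
  prof <- mk_calls(rbind(c(1L, 1L, 0L, -1L), c(1L, 0L, 0L, -1L)))
  a <- agree_similarity(prof)
  expect_equal(unname(a["s1", "s2"]), 0.75)
  expect_equal(unname(diag(a)), c(1, 1))
  expect_equal(unname(agree_similarity(
    mk_calls(rbind(c(1L, 1L), c(-1L, -1L))))["s1", "s2"]), 0)
})

test_that("conc is the fraction of concordantly ordered probe pairs", {
  prof <- mk_calls(rbind(c(-1L, 0L, 1L), c(-1L, 1L, 0L)))
  cc <- conc_similarity(prof)
  expect_equal(unname(cc["s1", "s2"]), 2 / 3)
  expect_equal(unname(diag(cc)), c(1, 1))
  expect_equal(unname(conc_similarity(
    mk_calls(rbind(c(0L, 1L), c(1L, 0L))))["s1", "s2"]), 0)
})

test_that("conc matches the O(P^2) probe-pair oracle", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(2:5, 1))
    p <- withr::with_seed(seed + 1, sample(3:12, 1))
    m <- random_call_matrix(n, p, seed + 3)
    cc <- conc_similarity(mk_calls(m))
    for (i in seq_len(n)) {
      for (j in i:n) {
        expect_equal(unname(cc[i, j]), oracle_conc_pair(m[i, ], m[j, ]),
                     info = paste("seed", seed))
      }
    }
  }
})

test_that("agree/conc live in [0,1]; agree ignores probe order, sim does not", {
  perm_prof <- function(m, perm) mk_calls(m[, perm, drop = FALSE])
  found_sim_change <- FALSE
  for (seed in 1:20) {
    m <- random_call_matrix(4, 10, seed + 60)
    prof <- mk_calls(m)
    a <- agree_similarity(prof)
    cc <- conc_similarity(prof)
    expect_true(all(a >= 0 & a <= 1) && all(diag(a) == 1))
    expect_true(all(cc >= 0 & cc <= 1) && all(abs(diag(cc) - 1) < 1e-12))
    expect_lt(max(abs(a - t(a))), 1e-12)
    expect_lt(max(abs(cc - t(cc))), 1e-12)
    perm <- withr::with_seed(seed, sample(10))
    expect_equal(unclass(agree_similarity(perm_prof(m, perm)))[, ],
                 unclass(a)[, ])
    s0 <- sim_similarity(prof)
    s1 <- sim_similarity(perm_prof(m, perm))
    if (!identical(unclass(s0)[, ], unclass(s1)[, ])) {
      found_sim_change <- TRUE
    }
    expect_equal(max(abs(s0 - t(unclass(s0)))), 0)
  }
  expect_true(found_sim_change)  # segment overlap depends on genome order
})

test_that("max-minus conversion yields a zero-diagonal dissimilarity", {
  s <- similarity_matrix(matrix(c(5, 2, 2, 4), 2,
                                dimnames = list(c("a", "b"), c("a", "b"))),
                         "sim_corrected")
  d <- similarity_to_dissimilarity(s)
  expect_equal(unname(d["a", "b"]), 3)
  expect_equal(unname(diag(d)), c(0, 0))

  const <- similarity_matrix(matrix(2, 3, 3), "agree")
  expect_true(all(similarity_to_dissimilarity(const) == 0))

  agree2 <- similarity_matrix(matrix(c(1, 0.75, 0.75, 1), 2,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b"))), "agree")
  d2 <- similarity_to_dissimilarity(agree2)
  expect_equal(unname(d2["a", "b"]), 0.25)
})

test_that("pairwise matrices tidy into long pair tibbles", {
  prof <- mk_calls(rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L)))
  td <- tidy(agree_similarity(prof))
  expect_equal(nrow(td), 3)
  expect_named(td, c("sample_a", "sample_b", "value", "measure"))
})
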