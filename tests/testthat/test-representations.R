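test_that("pca_compress keeps the smallest component set reaching the target", {
  # rank-1 data: one component explains everything
  base <- c(1, 2, 3, 4)
  m <- outer(c(1, 2, 3), base) + 5
  prof <- mk_logratio(m)
  pc <- pca_compress(prof, 0.90)
  expect_equal(attr(pc, "n_components"), 1L)
  expect_equal(sum(attr(pc, "explained_variance")), 1, tolerance = 1e-9)

  # two orthogonal centered coordinates with exact sample variances 9 and 1:
  # the covariance matrix is diag(9, 1), so PC1 explains exactly 90%
  x1 <- c(-3, -1, 1, 3) * sqrt(27 / 20)
  x2 <- c(1, -1, -1, 1) * sqrt(3 / 4)
  m2 <- cbind(x1, x2)
  expect_equal(var(m2[, 1]), 9, tolerance = 1e-9)
  expect_equal(var(m2[, 2]), 1, tolerance = 1e-9)
  prof2 <- mk_logratio(m2)
  expect_equal(attr(pca_compress(prof2, 0.90), "n_components"), 1L)
  expect_equal(attr(pca_compress(prof2, 0.999), "n_components"), 2L)
})

test_that("pca_compress rejects degenerate input", {
  expect_error(pca_compress(mk_logratio(matrix(1, 3, 4)), 0.9),
               "zero total variance")
  expect_error(pca_compress(mk_logratio(matrix(1:4, 1)), 0.9),
               "at least 2 samples")
})

test_that("pca scores are invariant to sample order up to column signs", {
  m <- withr::with_seed(7, matrix(rnorm(60), 6, 10))
  prof <- mk_logratio(m)
  pc1 <- pca_compress(prof, 0.95)
  perm <- c(4, 2, 6, 1, 3, 5)
  prof2 <- profile_select_samples(prof, paste0("s", perm))
  pc2 <- pca_compress(prof2, 0.95)
  a <- as.matrix(pc1[match(pc2$sample_id, pc1$sample_id), -1])
  b <- as.matrix(pc2[, -1])
  expect_equal(ncol(a), ncol(b))
  for (j in seq_len(ncol(a))) {
    expect_true(isTRUE(all.equal(a[, j], b[, j], tolerance = 1e-8,
                                 check.attributes = FALSE)) ||
                  isTRUE(all.equal(a[, j], -b[, j], tolerance = 1e-8,
                                   check.attributes = FALSE)))
  }
})

test_that("the worked minimal-region example yields exactly four regions", {
  C <- rbind(c(1L, 1L, 0L, 0L, -1L),
             c(1L, 1L, 1L, 0L, -1L),
             c(0L, 1L, 1L, 0L, 0L))
  mr <- extract_minimal_regions(mk_calls(C), 0.5)
  expect_equal(nrow(mr), 4)
  expect_equal(mr$start_idx, c(0L, 1L, 1L, 4L))
  expect_equal(mr$end_idx, c(2L, 2L, 3L, 5L))
  expect_equal(mr$alteration, c(1L, 1L, 1L, -1L))
  expect_equal(mr$support,
               list(c("s1", "s2"), c("s1", "s2", "s3"), c("s2", "s3"),
                    c("s1", "s2")))

  feats <- mr_membership_matrix(mr)
  fm <- as.matrix(feats[, -1])
  expect_equal(unname(colSums(fm)), c(2, 3, 2, 2))
  expect_true(all(fm %in% c(0, 1)))
})

test_that("degenerate minimal-region inputs behave per contract", {
  expect_equal(nrow(extract_minimal_regions(mk_calls(matrix(0L, 3, 5)),
                                            0.2)), 0)
  one <- extract_minimal_regions(mk_calls(matrix(c(1L, 1L), 1)), 1.0)
  expect_equal(nrow(one), 1)
  expect_equal(one$start_idx, 0L)
  expect_equal(one$end_idx, 2L)
  expect_equal(one$support[[1]], "s1")
  expect_error(
    mr_membership_matrix(
      extract_minimal_regions(mk_calls(matrix(0L, 2, 3)), 0.5)),
    "lower min_support_fraction")
})

test_that("minimal regions match the all-intervals oracle on random data", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(2:8, 1))
    p <- withr::with_seed(seed + 1, sample(4:20, 1))
    m <- random_call_matrix(n, p, seed + 2)
    chrom <- sort(withr::with_seed(seed + 3,
                                   sample(c("1", "2"), p, replace = TRUE)))
    fraction <- withr::with_seed(seed + 4, sample(c(0.2, 0.4, 0.6), 1))
    mr <- extract_minimal_regions(mk_calls(m, chrom = chrom), fraction)
    got <- mrset_as_oracle_frame(mr)
    want <- oracle_minimal_regions(m, chrom, fraction)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got[order(got$chromosome, got$start_idx,
                               got$alteration, got$end_idx), ],
                     want[order(want$chromosome, want$start_idx,
                                want$alteration, want$end_idx), ],
                     info = paste("seed", seed))
  }
})

test_that("no two regions share (chromosome, alteration, support) nested", {
  for (seed in 1:25) {
    m <- random_call_matrix(5, 15, seed + 500)
    mr <- extract_minimal_regions(mk_calls(m), 0.2)
    if (nrow(mr) < 2) next
    key <- paste(mr$chromosome, mr$alteration,
                 vapply(mr$support, paste, "", collapse = ","))
    for (g in split(seq_len(nrow(mr)), key)) {
      if (length(g) < 2) next
      for (i in g) {
        for (j in setdiff(g, i)) {
          nested <- mr$start_idx[i] <= mr$start_idx[j] &&
            mr$end_idx[i] >= mr$end_idx[j]
          expect_false(nested && !(mr$start_idx[i] == mr$start_idx[j] &&
                                     mr$end_idx[i] == mr$end_idx[j]))
        }
      }
    }
  }
})

test_that("minimal regions export as BED-like TSV", {
  C <- rbind(c(1L, 1L, 0L), c(1L, 1L, -1L))
  mr <- extract_minimal_regions(mk_calls(C), 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mrset_bed(mr, path)
  bed <- read.delim(path)
  expect_equal(nrow(bed), nrow(mr))
  expect_named(bed, c("chrom", "start", "end", "alteration", "n_support",
                      "support"))
})
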