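#' Configure the synthetic copy-number cohort generator
#'
#' Defaults emulate the structure of published BAC array-CGH tumor
#' cohorts: a few dozen tumors, a couple of thousand autosomal probes on
#' 22 chromosomes, latent classes sharing contiguous altered regions,
#' sporadic call noise, and missing values at a rate within the 3-13%
#' range typical of such data.
#'
#' @param n_samples Cohort size (default 48).
#' @param n_probes Total probes, split evenly over chromosomes (default
#'   2000).
#' @param n_chromosomes Autosome count (default 22).
#' @param n_clusters Latent classes (default 3); samples are assigned
#'   round-robin.
#' @param regions_per_cluster Contiguous altered regions owned by each
#'   class (default 2); regions are pairwise disjoint across classes so
#'   the ground truth is unambiguous at zero noise.
#' @param region_length Integer range (probes) of region lengths, default
#'   c(10, 30).
#' @param alteration_weights Sampling weights of the alteration types
#'   loss (-1), gain (1), amplification (2).
#' @param noise_rate Per-entry probability that a call is corrupted to a
#'   different random call (default 0.05).
#' @param missing_rate Per-entry missing probability (default 0.08).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 48L, n_probes = 2000L,
                             n_chromosomes = 22L, n_clusters = 3L,
                             regions_per_cluster = 2L,
                             region_length = c(10L, 30L),
                             alteration_weights = c(loss = 0.3, gain = 0.5,
                                                    amp = 0.2),
                             noise_rate = 0.05, missing_rate = 0.08,
                             seed = 1L) {
  stopifnot(n_clusters <= n_samples, noise_rate >= 0, noise_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            length(region_length) == 2, region_length[1] >= 1,
            region_length[2] >= region_length[1],
            length(alteration_weights) == 3, all(alteration_weights >= 0))
  structure(list(n_samples = as.integer(n_samples),
                 n_probes = as.integer(n_probes),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_clusters = as.integer(n_clusters),
                 regions_per_cluster = as.integer(regions_per_cluster),
                 region_length = as.integer(region_length),
                 alteration_weights = alteration_weights,
                 noise_rate = noise_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic called copy-number cohort
#'
#' Samples are assigned round-robin to latent classes; each class owns
#' `regions_per_cluster` contiguous probe intervals, disjoint across
#' classes (with a one-probe buffer so planted regions never fuse), set to
#' one sampled alteration type for all its members. All remaining entries
#' are normal (0). Each entry is then independently corrupted to a random
#' different call with probability `noise_rate` and masked as missing with
#' probability `missing_rate`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `profile` (calls `cgh_profile`, possibly with
#'   missing values), `labels` (tibble `sample_id`, `cluster`), and
#'   `regions` (tibble of the planted regions: cluster, chromosome,
#'   0-based half-open probe bounds on genome order, alteration).
#' @export
generate_call_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, generate_call_dataset_impl(cfg))
}

generate_call_dataset_impl <- function(cfg) {
  n <- cfg$n_samples
  p <- cfg$n_probes
  per_chrom <- diff(round(seq(0, p, length.out = cfg$n_chromosomes + 1L)))
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), per_chrom)
  position <- unlist(lapply(per_chrom, function(np) seq_len(np) * 1e5))
  probe_id <- sprintf("probe_%05d", seq_len(p))
  clusters <- ((seq_len(n) - 1L) %% cfg$n_clusters) + 1L
  sample_id <- sprintf("s%03d", seq_len(n))

  n_regions <- cfg$n_clusters * cfg$regions_per_cluster
  lengths <- sample(seq(cfg$region_length[1], cfg$region_length[2]),
                    n_regions, replace = TRUE)
  occupied <- logical(p)   # includes 1-probe buffers around placed regions
  regions <- vector("list", n_regions)
  alts <- c(-1L, 1L, 2L)
  for (r in seq_len(n_regions)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      ch <- sample(cfg$n_chromosomes, 1L)
      cols <- which(chrom == as.character(ch))
      if (length(cols) < lengths[r]) next
      s <- sample(length(cols) - lengths[r] + 1L, 1L)
      span <- cols[s:(s + lengths[r] - 1L)]
      if (any(occupied[span])) next
      occupied[max(1L, span[1] - 1L):min(p, span[length(span)] + 1L)] <- TRUE
      regions[[r]] <- tibble(
        cluster = ((r - 1L) %% cfg$n_clusters) + 1L,
        chromosome = as.character(ch),
        start_idx = span[1] - 1L, end_idx = span[length(span)],
        alteration = sample(alts, 1L, prob = cfg$alteration_weights))
      placed <- TRUE
      break
    }
    if (!placed) {
      abort("could not place the requested regions disjointly; reduce their number or length")
    }
  }
  regions <- dplyr::bind_rows(regions)

  m <- matrix(0L, nrow = n, ncol = p, dimnames = list(sample_id, probe_id))
  for (r in seq_len(nrow(regions))) {
    members <- clusters == regions$cluster[r]
    m[members, (regions$start_idx[r] + 1L):regions$end_idx[r]] <-
      regions$alteration[r]
  }
  if (cfg$noise_rate > 0) {
    flip <- matrix(stats::runif(n * p) < cfg$noise_rate, n, p)
    if (any(flip)) {
      cur <- m[flip]
      # draw uniformly among the three other call states
      shift <- sample.int(3L, sum(flip), replace = TRUE)
      states <- c(-1L, 0L, 1L, 2L)
      pos <- match(cur, states)
      m[flip] <- states[((pos - 1L + shift) %% 4L) + 1L]
    }
  }
  if (cfg$missing_rate > 0) {
    m[matrix(stats::runif(n * p) < cfg$missing_rate, n, p)] <- NA_integer_
  }

  df <- tibble(probe_id = probe_id, chromosome = chrom,
               position = position)
  for (i in seq_len(n)) df[[sample_id[i]]] <- m[i, ]
  list(profile = cgh_profile(df, kind = "calls"),
       labels = tibble(sample_id = sample_id, cluster = clusters),
       regions = regions)
}

#' Convert calls to noisy logratios
#'
#' Maps each call to its diploid copy-number mean on the base-2 log scale
#' (loss -1 -> -1, normal 0 -> 0, gain 1 -> log2(3/2), amplification 2 ->
#' log2(4/2) = 1, i.e. amplification modelled as four copies) and adds
#' Gaussian noise. Missing entries propagate.
#'
#' @param x A calls `cgh_profile`.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @param seed Integer seed.
#' @param mu Named numeric vector giving the log2 mean of each call state.
#' @return A logratio `cgh_profile`.
#' @export
calls_to_logratios <- function(x, noise_sd = 0.2, seed = 1L,
                               mu = c(`-1` = -1, `0` = 0,
                                      `1` = log2(3 / 2), `2` = 1)) {
  stopifnot(inherits(x, "cgh_profile"), profile_kind(x) == "calls")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  out <- as_tibble(x)
  withr::with_seed(seed, {
    for (s in profile_samples(x)) {
      v <- mu[as.character(out[[s]])]
      keep_na <- is.na(out[[s]])
      v <- v + stats::rnorm(length(v), 0, noise_sd)
      v[keep_na] <- NA_real_
      out[[s]] <- unname(v)
    }
  })
  new_cgh_profile(out, "logratio")
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard TSV matrix format plus a two-column label TSV.
#'
#' @param dataset Result of [generate_call_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cgh_profile(dataset$profile, file.path(dir, "calls.tsv"))
  utils::write.table(dataset$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
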