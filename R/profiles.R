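#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

PROFILE_KINDS <- c("calls", "logratio", "smoothed")
CALL_VALUES <- c(-1L, 0L, 1L, 2L)
SEX_CHROM_LABELS <- c("x", "y", "chrx", "chry", "23", "24")

#' Construct a copy-number profile tibble
#'
#' A CGH profile is a tibble with one row per probe, in genome order, holding
#' three annotation columns (`probe_id`, `chromosome`, `position`) followed by
#' one numeric column per sample. Calls profiles are restricted to the
#' discrete states loss (-1), normal (0), gain (1) and amplification (2);
#' logratio and smoothed-logratio profiles hold base-2 log scale reals.
#' Sex chromosomes are excluded on construction; autosomal probes are sorted
#' by chromosome then position.
#'
#' @param data A data frame with columns `probe_id`, `chromosome`, `position`
#'   and one column per sample.
#' @param kind One of `"calls"`, `"logratio"`, `"smoothed"`.
#' @return A `cgh_profile` tibble (probes in rows, samples in columns) with
#'   attribute `kind`.
#' @examples
#' df <- data.frame(probe_id = c("p1", "p2"), chromosome = "1",
#'                  position = c(100, 200), s1 = c(0, 1), s2 = c(-1, 0))
#' cgh_profile(df, kind = "calls")
#' @export
cgh_profile <- function(data, kind = c("calls", "logratio", "smoothed")) {
  kind <- match.arg(kind)
  data <- as_tibble(data)
  ann_cols <- c("probe_id", "chromosome", "position")
  missing_cols <- setdiff(ann_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("malformed profile: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  sample_ids <- setdiff(names(data), ann_cols)
  if (length(sample_ids) == 0) abort("profile has no sample columns")
  if (anyDuplicated(data$probe_id)) {
    dup <- unique(data$probe_id[duplicated(data$probe_id)])
    abort(paste0("duplicate probe_id: ", paste(dup, collapse = ", ")))
  }
  data$chromosome <- as.character(data$chromosome)
  data$position <- as.numeric(data$position)
  if (anyNA(data$position) || any(data$position < 0)) {
    abort("probe positions must be non-negative numbers")
  }
  # drop sex chromosomes; only autosomes are analysed
  sex <- tolower(data$chromosome) %in% SEX_CHROM_LABELS
  data <- data[!sex, , drop = FALSE]
  if (nrow(data) == 0) abort("no autosomal probes left after filtering")
  data <- data[order(chromosome_rank(data$chromosome), data$position), ,
               drop = FALSE]
  for (s in sample_ids) {
    v <- data[[s]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v) & as.character(v) != "NA")
      if (length(bad) > 0) {
        abort(paste0("non-numeric value in sample '", s, "', probe '",
                     data$probe_id[bad[1]], "'"))
      }
      v <- suppressWarnings(as.numeric(as.character(v)))
    }
    if (kind == "calls") {
      bad <- which(!is.na(v) & !(v %in% CALL_VALUES))
      if (length(bad) > 0) {
        abort(paste0("call out of range {-1,0,1,2} in sample '", s,
                     "', probe '", data$probe_id[bad[1]], "': ", v[bad[1]]))
      }
      v <- as.integer(v)
    }
    data[[s]] <- v
  }
  new_cgh_profile(data, kind)
}

new_cgh_profile <- function(data, kind) {
  structure(data,
            kind = kind,
            class = c("cgh_profile", class(as_tibble(data))))
}

# numeric-aware ordering of autosome labels ("chr2" < "chr10")
chromosome_rank <- function(chrom) {
  stripped <- sub("^chr", "", tolower(chrom))
  num <- suppressWarnings(as.numeric(stripped))
  ifelse(is.na(num), rank(stripped, ties.method = "min") + 1e6, num)
}

#' @export
print.cgh_profile <- function(x, ...) {
  cat("<cgh_profile> kind:", profile_kind(x), "-",
      length(profile_samples(x)), "samples x", nrow(x), "probes\n")
  NextMethod()
}

#' Profile accessors
#'
#' `profile_kind()` returns the representation kind; `profile_samples()` the
#' sample ids; `profile_annotation()` the probe annotation (with a 0-based
#' `order_index` giving genome order); `profile_matrix()` the samples x
#' probes numeric matrix.
#'
#' @param x A `cgh_profile`.
#' @return See each description.
#' @export
profile_kind <- function(x) attr(x, "kind")

#' @rdname profile_kind
#' @export
profile_samples <- function(x) {
  setdiff(names(x), c("probe_id", "chromosome", "position"))
}

#' @rdname profile_kind
#' @export
profile_annotation <- function(x) {
  tibble(probe_id = x$probe_id, chromosome = x$chromosome,
         position = x$position, order_index = seq_len(nrow(x)) - 1L)
}

#' @rdname profile_kind
#' @export
profile_matrix <- function(x) {
  samples <- profile_samples(x)
  m <- t(as.matrix(as_tibble(x)[samples]))
  dimnames(m) <- list(samples, x$probe_id)
  m
}

#' Keep a subset of samples in a profile
#'
#' @param x A `cgh_profile`.
#' @param samples Character vector of sample ids or integer indices.
#' @return A `cgh_profile` restricted to those samples, probes unchanged.
#' @export
profile_select_samples <- function(x, samples) {
  all_ids <- profile_samples(x)
  if (is.numeric(samples)) samples <- all_ids[samples]
  if (!all(samples %in% all_ids)) abort("unknown sample id(s)")
  new_cgh_profile(as_tibble(x)[c("probe_id", "chromosome", "position",
                                 samples)],
                  profile_kind(x))
}

#' Read a probe-annotated copy-number matrix from TSV
#'
#' Expects a tab-separated file with header columns `probe_id`,
#' `chromosome`, `position` followed by one column per sample; missing
#' entries are encoded `NA`. Sex-chromosome rows (X/Y/chrX/chrY/23/24) are
#' dropped and probes are sorted into genome order. For `kind = "calls"`
#' any value outside \{-1, 0, 1, 2, NA\} is an error naming the probe and
#' sample. The observed missing-value fraction is reported with a message.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"calls"`, `"logratio"`, `"smoothed"`.
#' @return A [cgh_profile()] tibble.
#' @export
read_cgh_profile <- function(path, kind = c("calls", "logratio", "smoothed")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = "NA", check.names = FALSE,
                          stringsAsFactors = FALSE)
  prof <- cgh_profile(df, kind = kind)
  frac <- missing_fraction(prof)
  message(sprintf("read %d samples x %d probes (%s); missing fraction %.3f",
                  length(profile_samples(prof)), nrow(prof), kind, frac))
  prof
}

#' @rdname read_cgh_profile
#' @param x A `cgh_profile` to write.
#' @export
write_cgh_profile <- function(x, path) {
  utils::write.table(as_tibble(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

missing_fraction <- function(x) {
  m <- profile_matrix(x)
  mean(is.na(m))
}

#' Impute missing copy-number values
#'
#' Deterministic within-chromosome imputation. For calls, a missing value
#' takes the call of the nearest non-missing probe on the same chromosome
#' for that sample (ties in genomic distance resolved toward the lower
#' genome order index); this respects the fact that neighboring genomic
#' segments tend to be altered in the same way. For logratios, values are
#' linearly interpolated in genomic position within each chromosome with
#' constant extrapolation at the chromosome ends.
#'
#' @param x A `cgh_profile` (any kind).
#' @return The same profile with no missing entries. Idempotent; never
#'   changes a non-missing entry.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "cgh_profile"))
  kind <- profile_kind(x)
  samples <- profile_samples(x)
  out <- as_tibble(x)
  chrom <- x$chromosome
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- x$position[idx]
    for (s in samples) {
      v <- out[[s]][idx]
      if (!anyNA(v)) next
      obs <- which(!is.na(v))
      if (length(obs) == 0) {
        abort(paste0("sample '", s, "' has no observed value on chromosome ",
                     ch, "; cannot impute"))
      }
      mis <- which(is.na(v))
      if (kind == "calls") {
        for (i in mis) {
          d <- abs(pos[obs] - pos[i])
          # tie in genomic distance -> lower order index (earlier probe)
          v[i] <- v[obs[which.min(d)]]
        }
      } else {
        if (length(obs) == 1) {
          v[mis] <- v[obs]
        } else {
          v[mis] <- stats::approx(pos[obs], v[obs], xout = pos[mis],
                                  method = "linear", rule = 2,
                                  ties = "ordered")$y
        }
      }
      out[[s]][idx] <- v
    }
  }
  new_cgh_profile(out, kind)
}
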