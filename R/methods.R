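REPRESENTATIONS <- c("calls", "logratio", "smoothed", "pca", "mr")
MEASURES <- c("euclidean", "manhattan", "pearson", "sim", "agree", "conc")
ALGORITHMS <- c("complete", "average", "weighted", "ward", "diana",
                "kmeans", "kcentroids", "total")
CGH_MEASURES <- c("sim", "agree", "conc")

#' Define a class-discovery method
#'
#' A class-discovery method is the combination of an input data
#' representation, a dissimilarity measure and a clustering algorithm.
#' Compatibility rules: the copy-number-specific measures (`sim`, `agree`,
#' `conc`) apply only to the calls and minimal-region representations;
#' `kmeans` operates on the Euclidean geometry of a feature representation
#' (measure must be `euclidean`); `total` requires `agree` or `conc`.
#'
#' @param representation One of `"calls"`, `"logratio"`, `"smoothed"`,
#'   `"pca"`, `"mr"`.
#' @param measure One of `"euclidean"`, `"manhattan"`, `"pearson"`,
#'   `"sim"`, `"agree"`, `"conc"`.
#' @param algorithm One of `"complete"`, `"average"`, `"weighted"`,
#'   `"ward"`, `"diana"`, `"kmeans"`, `"kcentroids"`, `"total"`.
#' @param mr_fraction Minimal-region support fraction (used when
#'   `representation = "mr"`); default 0.2.
#' @param pca_var PCA variance fraction (used when
#'   `representation = "pca"`); default 0.90.
#' @param seed Base seed for stochastic algorithms.
#' @param restarts Restarts for `kmeans`/`kcentroids`.
#' @return A `cgh_method` object.
#' @export
method_spec <- function(representation, measure, algorithm,
                        mr_fraction = 0.2, pca_var = 0.90,
                        seed = 1L, restarts = 10L) {
  representation <- match.arg(representation, REPRESENTATIONS)
  measure <- match.arg(measure, MEASURES)
  algorithm <- match.arg(algorithm, ALGORITHMS)
  ok <- method_compatible(representation, measure, algorithm)
  if (!isTRUE(ok)) abort(paste0("incompatible method: ", ok))
  label <- paste(
    if (representation == "mr") sprintf("mr%.2f", mr_fraction) else
      representation,
    measure, algorithm, sep = "+")
  structure(list(representation = representation, measure = measure,
                 algorithm = algorithm, mr_fraction = mr_fraction,
                 pca_var = pca_var, seed = as.integer(seed),
                 restarts = as.integer(restarts), label = label),
            class = "cgh_method")
}

# TRUE when compatible, else a string explaining why not
method_compatible <- function(representation, measure, algorithm) {
  if (measure %in% CGH_MEASURES && !representation %in% c("calls", "mr")) {
    return(paste0(measure, " applies only to calls or minimal regions"))
  }
  if (algorithm == "kmeans" && measure != "euclidean") {
    return("kmeans is defined for the euclidean measure only")
  }
  if (algorithm == "total" && !measure %in% c("agree", "conc")) {
    return("total linkage is associated only with agree and conc")
  }
  TRUE
}

#' @export
print.cgh_method <- function(x, ...) {
  cat("<cgh_method>", x$label, "\n")
  invisible(x)
}

#' Bundle the representations of one cohort
#'
#' Holds the calls, logratio and/or smoothed-logratio profiles of the same
#' samples; downstream operations pick the profile a method's
#' representation needs.
#'
#' @param calls,logratio,smoothed `cgh_profile` objects (any may be NULL).
#' @return A `cgh_dataset` list.
#' @export
cgh_dataset <- function(calls = NULL, logratio = NULL, smoothed = NULL) {
  profs <- Filter(Negate(is.null), list(calls = calls, logratio = logratio,
                                        smoothed = smoothed))
  if (length(profs) == 0) abort("provide at least one profile")
  ids <- lapply(profs, profile_samples)
  if (length(unique(lapply(ids, sort))) > 1) {
    abort("profiles carry different sample sets")
  }
  structure(list(calls = calls, logratio = logratio, smoothed = smoothed,
                 sample_ids = ids[[1]]),
            class = "cgh_dataset")
}

#' @export
print.cgh_dataset <- function(x, ...) {
  have <- names(Filter(Negate(is.null),
                       x[c("calls", "logratio", "smoothed")]))
  cat("<cgh_dataset>", length(x$sample_ids), "samples; profiles:",
      paste(have, collapse = ", "), "\n")
  invisible(x)
}

dataset_samples <- function(data) data$sample_ids

dataset_subset <- function(data, samples) {
  pick <- function(p) if (is.null(p)) NULL else
    profile_select_samples(p, samples)
  cgh_dataset(calls = pick(data$calls), logratio = pick(data$logratio),
              smoothed = pick(data$smoothed))
}

dataset_impute <- function(data) {
  imp <- function(p) if (is.null(p)) NULL else impute_missing(p)
  cgh_dataset(calls = imp(data$calls), logratio = imp(data$logratio),
              smoothed = imp(data$smoothed))
}

need_profile <- function(data, which) {
  p <- data[[which]]
  if (is.null(p)) {
    abort(paste0("this method needs the '", which,
                 "' profile, which the dataset does not carry"))
  }
  p
}

#' Apply a class-discovery method to a cohort
#'
#' Builds the method's input representation (minimal regions and PCA are
#' fit on the given cohort), derives the dissimilarity or similarity it
#' needs and clusters the samples into `k` groups.
#'
#' @param data A `cgh_dataset` with imputed profiles (imputation is run on
#'   demand if missing values are present).
#' @param method A [method_spec()].
#' @param k Number of clusters.
#' @param seed Overrides the method's base seed for stochastic algorithms.
#' @return A `cgh_partition` (named integer vector, sample id -> cluster).
#' @export
build_partition <- function(data, method, k, seed = method$seed) {
  stopifnot(inherits(data, "cgh_dataset"), inherits(method, "cgh_method"))
  rep <- method$representation
  calls_src <- if (rep %in% c("calls", "mr")) need_profile(data, "calls")
  sim_input <- NULL      # calls profile or MR features for sim/agree/conc
  feats <- switch(
    rep,
    calls = as_features(calls_src),
    logratio = as_features(need_profile(data, "logratio")),
    smoothed = as_features(need_profile(data, "smoothed")),
    pca = pca_compress(need_profile(data, "logratio"), method$pca_var),
    mr = {
      mrs <- extract_minimal_regions(calls_src, method$mr_fraction)
      mr_membership_matrix(mrs)
    })
  if (method$measure %in% CGH_MEASURES) {
    sim_input <- if (rep == "mr") feats else calls_src
  }

  alg <- method$algorithm
  if (alg == "kmeans") {
    return(kmeans_cluster(feats, k, seed = seed, restarts = method$restarts))
  }
  if (alg == "total") {
    return(total_cluster(sim_input, measure = method$measure, k = k))
  }
  d <- method_dissimilarity(feats, sim_input, method)
  if (alg == "kcentroids") {
    return(kcentroids_cluster(d, k, seed = seed,
                              restarts = method$restarts))
  }
  tree <- if (alg == "diana") diana_cluster(d) else
    agglomerative_cluster(d, linkage = alg)
  cut_dendrogram(tree, k)
}

method_dissimilarity <- function(feats, sim_input, method) {
  switch(method$measure,
         euclidean = ,
         manhattan = ,
         pearson = vector_dissimilarity(feats, method$measure),
         sim = similarity_to_dissimilarity(
           correct_sim_diagonal(sim_similarity(sim_input))),
         agree = similarity_to_dissimilarity(agree_similarity(sim_input)),
         conc = similarity_to_dissimilarity(conc_similarity(sim_input)))
}
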