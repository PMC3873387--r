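# Sample stratification: disease datasets are split into
# expression-homogeneous subsets by K-means in the space of inflammation
# and cancer (IC) gene expression, then subsets below the minimum size are
# dropped; normal datasets pass through unclustered.

.new_stratification <- function(parent_id, subsets, k_used, dropped) {
  structure(list(parent_id = parent_id, subsets = subsets, k_used = k_used,
                 dropped_subsets = dropped),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("<stratification> %s: k = %s, %d subset(s) retained, %d dropped\n",
              x$parent_id, ifelse(is.na(x$k_used), "-", x$k_used),
              length(x$subsets), nrow(x$dropped_subsets)))
  invisible(x)
}

# size-suffixed subset ids in the style "GSE901_32"; collisions get a
# make.unique suffix
.subset_ids <- function(parent_id, sizes) {
  make.unique(paste0(parent_id, "_", sizes), sep = "x")
}

#' Stratify a disease dataset into expression-homogeneous subsets
#'
#' Samples are clustered by K-means in the space of the dataset's
#' inflammation and cancer gene expression: four clusters when the dataset
#' has more than 100 samples, two otherwise. Clusters smaller than
#' `min_samples` are recorded in `dropped_subsets` and excluded. Subset
#' identifiers are the parent id suffixed with the subset size
#' (e.g. `"GSE907_22"`).
#'
#' @param ds an [expression_dataset()] with a disease phenotype.
#' @param gs a [gene_sets()] object; the feature space is the rows of `ds`
#'   in the union of the inflammation and cancer sets (at least 2 required).
#' @param min_samples minimum retained subset size (default 20).
#' @param seed integer seed for the K-means initialisation (k-means++-style
#'   multiple restarts via `nstart = 25`).
#' @param standardize if TRUE, z-score each IC gene across samples first.
#' @return a `stratification` object; `subsets` is a named list of sample-id
#'   vectors.
#' @export
stratify_dataset <- function(ds, gs, min_samples = 20L, seed = 1L,
                             standardize = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(gs, "gene_sets"))
  ic <- intersect(ds$genes, .ic_genes(gs))
  if (length(ic) < 2L)
    stop("fewer than 2 inflammation/cancer genes present in the dataset")
  n <- length(ds$samples)
  k <- if (n > 100L) 4L else 2L
  if (n < k) stop("dataset has ", n, " samples; fewer than k = ", k)
  feat <- t(ds$values[ic, , drop = FALSE])
  if (standardize) feat <- scale(feat)
  cl <- .with_seed(seed, {
    stats::kmeans(feat, centers = k, nstart = 25L, iter.max = 100L)$cluster
  })
  groups <- split(ds$samples, cl)
  sizes <- lengths(groups)
  ids <- .subset_ids(ds$dataset_id, sizes)
  keep <- sizes >= min_samples
  dropped <- data.frame(subset_id = ids[!keep], size = unname(sizes[!keep]),
                        stringsAsFactors = FALSE)
  .new_stratification(ds$dataset_id,
                      stats::setNames(groups[keep], ids[keep]), k, dropped)
}

#' Pass a normal dataset through the size filter unclustered
#'
#' Normal datasets are taken as homogeneous: the whole sample set forms a
#' single subset if it reaches `min_samples`, otherwise it is dropped.
#'
#' @param ds an [expression_dataset()] with phenotype "normal".
#' @param min_samples minimum subset size (default 20).
#' @return a `stratification` object.
#' @export
passthrough_normal <- function(ds, min_samples = 20L) {
  stopifnot(inherits(ds, "expression_dataset"))
  n <- length(ds$samples)
  id <- .subset_ids(ds$dataset_id, n)
  if (n >= min_samples) {
    .new_stratification(ds$dataset_id,
                        stats::setNames(list(ds$samples), id), NA_integer_,
                        data.frame(subset_id = character(0),
                                   size = integer(0)))
  } else {
    .new_stratification(ds$dataset_id, list(), NA_integer_,
                        data.frame(subset_id = id, size = n,
                                   stringsAsFactors = FALSE))
  }
}

#' Materialise stratification subsets as expression datasets
#'
#' @param ds the parent [expression_dataset()].
#' @param strat a `stratification` of `ds`.
#' @return named list of [expression_dataset()] objects, one per retained
#'   subset.
#' @export
subset_datasets <- function(ds, strat) {
  stopifnot(inherits(strat, "stratification"),
            identical(ds$dataset_id, strat$parent_id))
  out <- lapply(names(strat$subsets), function(id) {
    .subset_samples(ds, strat$subsets[[id]], dataset_id = id)
  })
  stats::setNames(out, names(strat$subsets))
}
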