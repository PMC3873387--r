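#' Construct a phenotype-labelled expression dataset
#'
#' A light container for one genes x samples matrix of log2-scale expression
#' values together with a dataset identifier and a phenotype label
#' (typically one of `"normal"`, `"UC"`, `"CD"`, `"CRC"`, or a synthetic
#' condition name).
#'
#' @param values numeric matrix, rows = genes, columns = samples. Row and
#'   column names are used as gene and sample identifiers when `genes` /
#'   `samples` are not given.
#' @param dataset_id character scalar identifying the dataset.
#' @param phenotype character scalar phenotype label.
#' @param genes,samples optional identifier vectors overriding the dimnames.
#' @return an object of class `expression_dataset` with fields
#'   `dataset_id`, `phenotype`, `genes`, `samples`, `values`.
#' @export
expression_dataset <- function(values, dataset_id, phenotype,
                               genes = rownames(values),
                               samples = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(genes) || is.null(samples))
    stop("gene and sample identifiers are required")
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (length(genes) != nrow(values))
    stop("length(genes) must equal nrow(values)")
  if (length(samples) != ncol(values))
    stop("length(samples) must equal ncol(values)")
  if (ncol(values) < 1L) stop("at least one sample is required")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!all(is.finite(values))) stop("all expression values must be finite")
  dimnames(values) <- list(genes, samples)
  structure(list(dataset_id = as.character(dataset_id),
                 phenotype = as.character(phenotype),
                 genes = genes, samples = samples, values = values),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s [%s]: %d genes x %d samples\n",
              x$dataset_id, x$phenotype, length(x$genes), length(x$samples)))
  invisible(x)
}

# restrict to a subset of samples (used by stratification)
.subset_samples <- function(ds, sample_ids, dataset_id = ds$dataset_id) {
  expression_dataset(ds$values[, sample_ids, drop = FALSE],
                     dataset_id = dataset_id, phenotype = ds$phenotype)
}

#' Construct the three analysis gene sets
#'
#' Holds the transcription-factor set and the two phenotype gene sets
#' (inflammation and cancer, jointly the "IC" gene sets). Membership is
#' case-sensitive exact string matching, and a gene may belong to more than
#' one set; pairwise overlaps are reported by [print()] and by
#' [read_gene_sets()].
#'
#' @param tf_set,inflammation_set,cancer_set character vectors of gene
#'   identifiers; each must be non-empty. Duplicates within a set are
#'   removed.
#' @return an object of class `gene_sets`.
#' @export
gene_sets <- function(tf_set, inflammation_set, cancer_set) {
  sets <- list(tf_set = unique(as.character(tf_set)),
               inflammation_set = unique(as.character(inflammation_set)),
               cancer_set = unique(as.character(cancer_set)))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
  structure(sets, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> TF: %d, inflammation: %d, cancer: %d\n",
              length(x$tf_set), length(x$inflammation_set),
              length(x$cancer_set)))
  ov <- gene_set_overlaps(x)
  cat(sprintf("  overlaps: TF/inflammation %d, TF/cancer %d, inflammation/cancer %d\n",
              ov[["tf_inflammation"]], ov[["tf_cancer"]],
              ov[["inflammation_cancer"]]))
  invisible(x)
}

#' Pairwise overlap counts among the three gene sets
#'
#' @param gs a [gene_sets()] object.
#' @return named integer vector with elements `tf_inflammation`, `tf_cancer`
#'   and `inflammation_cancer`.
#' @export
gene_set_overlaps <- function(gs) {
  stopifnot(inherits(gs, "gene_sets"))
  c(tf_inflammation = length(intersect(gs$tf_set, gs$inflammation_set)),
    tf_cancer = length(intersect(gs$tf_set, gs$cancer_set)),
    inflammation_cancer = length(intersect(gs$inflammation_set,
                                           gs$cancer_set)))
}

# IC genes: union of the inflammation and cancer sets
.ic_genes <- function(gs) union(gs$inflammation_set, gs$cancer_set)
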