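# Readers and writers for the plain-text formats the pipeline touches:
# tab-separated expression matrices, gene-set lists (one-per-line or GMT),
# and SIF network files with TSV attribute sidecars for Cytoscape.
#
# The only accepted dialect is '\t'-delimited with '.' as decimal separator;
# anything else fails loudly rather than being guessed at.

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body must be numeric. Values are taken as already being
#' on the log2 scale unless `apply_log2 = TRUE`, in which case
#' `log2(x + 1)` is applied (for raw-scale inputs). Rows with an empty gene
#' identifier are dropped with a warning; duplicate gene identifiers are an
#' error (probe-to-gene mapping is expected to have happened upstream).
#'
#' @param path path to the TSV file.
#' @param dataset_id identifier recorded on the returned dataset.
#' @param phenotype phenotype label (e.g. "normal", "UC", "CD", "CRC").
#' @param apply_log2 if TRUE, transform values by `log2(x + 1)`.
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(path, dataset_id, phenotype,
                                   apply_log2 = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("malformed expression file '", path, "': need a header and at ",
         "least one data row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in '", path, "': expected tab-separated sample ",
         "identifiers after the gene-id column")
  samples <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, character(1), 1L)
  keep <- nzchar(trimws(ids))
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with empty gene identifier dropped")
    rows <- rows[keep]
    ids <- ids[keep]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifier(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(samples) + 1L)
      stop("row for gene '", ids[i], "' has ", length(r) - 1L,
           " values; expected ", length(samples))
    v <- suppressWarnings(as.numeric(r[-1]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric value '", r[-1][bad[1]], "' at gene '", ids[i],
           "', sample '", samples[bad[1]], "'")
    vals[i, ] <- v
  }
  if (apply_log2) vals <- log2(vals + 1)
  expression_dataset(vals, dataset_id = dataset_id, phenotype = phenotype)
}

#' Write an expression dataset as TSV
#'
#' Values are printed with a fixed 6-decimal format so that a
#' write/read/write round trip reproduces the file byte-identically.
#'
#' @param ds an [expression_dataset()].
#' @param path output path.
#' @export
write_expression_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", ds$samples), collapse = "\t"), con)
  body <- vapply(seq_along(ds$genes), function(i) {
    paste(c(ds$genes[i], sprintf("%.6f", ds$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

# one file: either a one-gene-per-line list or a single GMT record
.read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty gene-set file: '", path, "'")
  fields <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L && length(fields) >= 3L) {
    return(fields[-(1:2)])  # GMT: name, description, members...
  }
  unlist(strsplit(lines, "\t", fixed = TRUE), use.names = FALSE)
}

#' Read the TF, inflammation and cancer gene sets
#'
#' Each file is either a one-gene-per-line list or a single GMT record
#' (set name, description, then members). Pairwise overlap counts among the
#' three sets are reported as a message; overlapping membership is allowed
#' and retained.
#'
#' @param tf_path,infl_path,cancer_path file paths.
#' @return a [gene_sets()] object.
#' @export
read_gene_sets <- function(tf_path, infl_path, cancer_path) {
  gs <- gene_sets(tf_set = .read_gene_list(tf_path),
                  inflammation_set = .read_gene_list(infl_path),
                  cancer_set = .read_gene_list(cancer_path))
  ov <- gene_set_overlaps(gs)
  message(sprintf(
    "gene-set overlaps: TF/inflammation %d, TF/cancer %d, inflammation/cancer %d",
    ov[["tf_inflammation"]], ov[["tf_cancer"]], ov[["inflammation_cancer"]]))
  gs
}

# node role string from flags, e.g. "TF+inflammation"
.node_role <- function(is_tf, is_inflammation, is_cancer) {
  parts <- mapply(function(t, i, c) {
    p <- c(if (t) "TF", if (i) "inflammation", if (c) "cancer")
    if (length(p) == 0L) "other" else paste(p, collapse = "+")
  }, is_tf, is_inflammation, is_cancer)
  as.character(parts)
}

#' Export a regulatory network for Cytoscape
#'
#' Writes a SIF file (`TF <tab> regulates <tab> gene`, one line per edge)
#' plus two TSV sidecars: an edge-attribute table (`tf`, `gene`, `mi`, and
#' any extra per-edge columns present) and a node-attribute table
#' (`node`, `role`).
#'
#' @param network a `regnet` object (see [regulatory_network()]).
#' @param path path of the SIF file; the sidecars get `.edges.tsv` and
#'   `.nodes.tsv` appended to `path` stripped of its extension.
#' @return invisibly, the three paths written.
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "regnet"))
  base <- sub("\\.sif$", "", path)
  edge_path <- paste0(base, ".edges.tsv")
  node_path <- paste0(base, ".nodes.tsv")
  e <- network$edges
  writeLines(if (nrow(e)) paste(e$tf, "regulates", e$gene, sep = "\t")
             else character(0), path)
  emat <- e
  num <- vapply(emat, is.numeric, logical(1))
  emat[num] <- lapply(emat[num], function(v) sprintf("%.10g", v))
  writeLines(c(paste(names(emat), collapse = "\t"),
               if (nrow(emat)) do.call(paste, c(unname(emat), sep = "\t"))),
             edge_path)
  nd <- network$nodes
  writeLines(c("node\trole",
               if (nrow(nd)) paste(nd$gene,
                                   .node_role(nd$is_tf, nd$is_inflammation,
                                              nd$is_cancer), sep = "\t")),
             node_path)
  invisible(c(sif = path, edges = edge_path, nodes = node_path))
}

#' Read a network written by [write_network_sif()]
#'
#' Reconstructs a `regnet` object from the SIF file and its attribute
#' sidecars; the round trip preserves the node set, edge set and MI weights
#' to full printed precision.
#'
#' @param path path of the SIF file (sidecars located as in
#'   [write_network_sif()]).
#' @param network_id,phenotype metadata for the reconstructed network.
#' @return a `regnet` object.
#' @export
read_network_sif <- function(path, network_id = basename(path),
                             phenotype = NA_character_) {
  base <- sub("\\.sif$", "", path)
  ef <- paste0(base, ".edges.tsv")
  nf <- paste0(base, ".nodes.tsv")
  edges <- utils::read.delim(ef, stringsAsFactors = FALSE,
                             colClasses = NA)
  nodes <- utils::read.delim(nf, stringsAsFactors = FALSE)
  roles <- strsplit(nodes$role, "+", fixed = TRUE)
  node_df <- data.frame(
    gene = nodes$node,
    is_tf = vapply(roles, function(r) "TF" %in% r, logical(1)),
    is_inflammation = vapply(roles, function(r) "inflammation" %in% r,
                             logical(1)),
    is_cancer = vapply(roles, function(r) "cancer" %in% r, logical(1)),
    stringsAsFactors = FALSE)
  regulatory_network(edges = edges, nodes = node_df,
                     network_id = network_id, phenotype = phenotype)
}

#' Read a YAML run configuration
#'
#' Convenience wrapper: a run config lists input paths (expression matrices
#' with their dataset ids and phenotype labels, gene-set files) and analysis
#' parameters; this returns it as a named list.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
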