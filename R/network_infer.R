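# Regulatory-network reconstruction: pairwise TF-gene mutual information,
# permutation-calibrated significance threshold, data-processing-inequality
# pruning, and extraction of the IC-specific largest connected component.

#' Construct a regulatory network object
#'
#' A `regnet` holds an undirected TF-anchored edge list with MI weights and
#' a node table with role flags. Every edge must have at least one TF
#' endpoint; edges are stored with the TF endpoint first (for TF-TF edges,
#' the lexicographically smaller identifier first); self-edges are
#' forbidden.
#'
#' @param edges data.frame with columns `tf`, `gene`, `mi` (extra columns
#'   are kept).
#' @param nodes data.frame with columns `gene`, `is_tf`, `is_inflammation`,
#'   `is_cancer`; defaults to the nodes appearing in `edges` if a
#'   `gene_sets` object is supplied via `gs`.
#' @param network_id,phenotype metadata strings.
#' @param gs optional [gene_sets()] used to build `nodes` when absent.
#' @param provenance optional named list (subset id, n_samples, cutoffs).
#' @return object of class `regnet`.
#' @export
regulatory_network <- function(edges, nodes = NULL, network_id = "net",
                               phenotype = NA_character_, gs = NULL,
                               provenance = list()) {
  stopifnot(is.data.frame(edges),
            all(c("tf", "gene") %in% names(edges)))
  if (!"mi" %in% names(edges)) edges$mi <- NA_real_
  edges$tf <- as.character(edges$tf)
  edges$gene <- as.character(edges$gene)
  if (any(edges$tf == edges$gene)) stop("self-edges are not allowed")
  if (any(!is.na(edges$mi) & edges$mi < 0)) stop("MI weights must be >= 0")
  if (is.null(nodes)) {
    if (is.null(gs)) stop("either nodes or gs must be supplied")
    ids <- sort(unique(c(edges$tf, edges$gene)))
    nodes <- data.frame(gene = ids,
                        is_tf = ids %in% gs$tf_set,
                        is_inflammation = ids %in% gs$inflammation_set,
                        is_cancer = ids %in% gs$cancer_set,
                        stringsAsFactors = FALSE)
  }
  is_tf <- stats::setNames(nodes$is_tf, nodes$gene)
  missing_nodes <- setdiff(unique(c(edges$tf, edges$gene)), nodes$gene)
  if (length(missing_nodes))
    stop("edge endpoints absent from the node table: ",
         paste(utils::head(missing_nodes, 5), collapse = ", "))
  if (nrow(edges) && any(!is_tf[edges$tf]))
    stop("every edge must have a TF endpoint in the 'tf' column")
  # canonical order: TF-TF edges lexicographically smaller first
  both_tf <- nrow(edges) > 0 & is_tf[edges$tf] &
    (edges$gene %in% nodes$gene[nodes$is_tf])
  flip <- both_tf & edges$gene < edges$tf
  if (any(flip)) {
    tmp <- edges$tf[flip]
    edges$tf[flip] <- edges$gene[flip]
    edges$gene[flip] <- tmp
  }
  edges <- edges[!duplicated(edges[c("tf", "gene")]), , drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(network_id = as.character(network_id),
                 phenotype = as.character(phenotype),
                 nodes = nodes, edges = edges, provenance = provenance),
            class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf("<regnet> %s [%s]: %d nodes (%d TFs), %d edges\n",
              x$network_id, x$phenotype, nrow(x$nodes), sum(x$nodes$is_tf),
              nrow(x$edges)))
  invisible(x)
}

# undirected igraph view of a regnet (or of a raw edge data.frame)
.as_igraph <- function(x) {
  edges <- if (inherits(x, "regnet")) x$edges else x
  vertices <- if (inherits(x, "regnet")) x$nodes$gene else
    sort(unique(c(edges$tf, edges$gene)))
  igraph::graph_from_data_frame(edges[c("tf", "gene")], directed = FALSE,
                                vertices = vertices)
}

#' Prune indirect edges with the data processing inequality
#'
#' For every fully connected triple of edges, the edge with the smallest MI
#' is marked for removal if its MI is at most `(1 - tolerance)` times the
#' smaller of the other two (so at tolerance 0 the weakest edge of every
#' triangle is removed, ties included). All triangles are evaluated against
#' the original weights and marked edges are deleted afterwards
#' (mark-then-delete, not sequential). When all three weights tie exactly,
#' the edge with the lexicographically smallest endpoint pair is removed.
#'
#' @param edges data.frame with columns `tf`, `gene`, `mi`.
#' @param tolerance DPI tolerance in `[0, 1]`; default 0.
#' @return the pruned edge data.frame.
#' @export
dpi_prune <- function(edges, tolerance = 0) {
  stopifnot(is.data.frame(edges), all(c("tf", "gene", "mi") %in% names(edges)))
  if (!(tolerance >= 0 && tolerance <= 1)) stop("tolerance must be in [0, 1]")
  if (nrow(edges) < 3L) return(edges)
  g <- .as_igraph(edges)
  tri <- igraph::triangles(g)
  if (length(tri) == 0L) return(edges)
  tri <- matrix(igraph::V(g)$name[tri], ncol = 3L, byrow = TRUE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ekey <- key(edges$tf, edges$gene)
  mi <- stats::setNames(edges$mi, ekey)
  drop <- character(0)
  for (r in seq_len(nrow(tri))) {
    v <- tri[r, ]
    ks <- c(key(v[1], v[2]), key(v[1], v[3]), key(v[2], v[3]))
    ms <- mi[ks]
    ord <- order(ms, ks)   # weakest first; exact ties by endpoint pair
    if (ms[ord[1]] <= (1 - tolerance) * min(ms[ord[2]], ms[ord[3]]))
      drop <- c(drop, ks[ord[1]])
  }
  out <- edges[!(ekey %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer a regulatory network from one expression dataset
#'
#' Candidate pairs are every (TF, other gene) pair, including TF-TF pairs;
#' non-TF gene pairs are never tested. MI is estimated for every candidate
#' pair, pairs at or above the permutation-calibrated threshold (see
#' [calibrate_mi_threshold()]) are kept, and the surviving edge set is
#' DPI-pruned. Node roles are annotated from the gene sets.
#'
#' @param dataset an [expression_dataset()] with at least 20 samples.
#' @param gs a [gene_sets()] object.
#' @param pvalue per-pair significance level (default 0.001).
#' @param dpi_tolerance DPI tolerance (default 0).
#' @param seed integer seed for the threshold calibration.
#' @param n_null number of null pairs for the calibration.
#' @param network_id identifier of the result (defaults to the dataset id).
#' @return a `regnet`.
#' @export
infer_network <- function(dataset, gs, pvalue = 0.001, dpi_tolerance = 0,
                          seed = 1L, n_null = 1e5,
                          network_id = dataset$dataset_id) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(gs, "gene_sets"))
  n <- length(dataset$samples)
  if (n < 20L)
    stop("dataset has ", n, " samples; at least 20 are required for ",
         "network reconstruction")
  # canonical gene order so results are invariant to input row order
  ord <- order(dataset$genes)
  dataset$genes <- dataset$genes[ord]
  dataset$values <- dataset$values[ord, , drop = FALSE]
  genes <- dataset$genes
  tfs <- intersect(genes, gs$tf_set)
  if (length(tfs) == 0L) stop("no TFs from the TF set present in the dataset")
  klist <- .kernel_list(dataset$values)
  idx <- stats::setNames(seq_along(genes), genes)
  # candidate pairs: TF x any other gene, TF-TF pairs deduplicated
  ii <- rep(idx[tfs], each = length(genes))
  jj <- rep(idx[genes], times = length(tfs))
  keep <- ii != jj & !(genes[jj] %in% tfs & genes[jj] < genes[ii])
  ii <- ii[keep]; jj <- jj[keep]
  mi <- .mi_pairs(klist, ii, jj, n)
  thr <- .calibrate_from_kernels(klist, n, pvalue, n_null, seed)
  sel <- mi >= thr
  edges <- data.frame(tf = genes[ii[sel]], gene = genes[jj[sel]],
                      mi = mi[sel], stringsAsFactors = FALSE)
  edges <- dpi_prune(edges, dpi_tolerance)
  regulatory_network(edges, gs = gs, network_id = network_id,
                     phenotype = dataset$phenotype,
                     provenance = list(dataset_id = dataset$dataset_id,
                                       n_samples = n,
                                       mi_pvalue_cutoff = pvalue,
                                       mi_threshold = thr,
                                       dpi_tolerance = dpi_tolerance,
                                       seed = seed))
}

# components of a regnet; returns membership vector named by gene
.components <- function(net) {
  g <- .as_igraph(net)
  igraph::components(g)$membership
}

#' Extract the IC-specific largest connected component
#'
#' Restricts a network to TFs and IC genes (edges whose non-TF endpoint is
#' an inflammation or cancer gene, or whose endpoints are both TFs), then
#' returns the largest connected component by node count, breaking size
#' ties by the lexicographically smallest node identifier.
#'
#' @param net a `regnet`.
#' @param gs a [gene_sets()] object.
#' @return a `regnet` restricted to the IC-specific component; its
#'   provenance gains `component_counts` (numbers of TFs, inflammation and
#'   cancer genes in the component).
#' @export
extract_ic_component <- function(net, gs) {
  stopifnot(inherits(net, "regnet"), inherits(gs, "gene_sets"))
  nd <- net$nodes
  ic <- .ic_genes(gs)
  tf_nodes <- nd$gene[nd$is_tf]
  e <- net$edges
  keep <- (e$gene %in% ic) | (e$gene %in% tf_nodes)
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0L)
    stop("IC-specific subnetwork is empty: ", nrow(net$edges),
         " edges in input, ", sum(nd$is_tf), " TF nodes, ",
         length(intersect(nd$gene, ic)), " IC nodes")
  sub_nodes <- nd[nd$gene %in% unique(c(e$tf, e$gene)), , drop = FALSE]
  sub <- regulatory_network(e, nodes = sub_nodes, network_id = net$network_id,
                            phenotype = net$phenotype,
                            provenance = net$provenance)
  memb <- .components(sub)
  sizes <- table(memb)
  big <- names(sizes)[sizes == max(sizes)]
  if (length(big) > 1L) {  # tie: component holding the smallest node id
    firsts <- vapply(big, function(b) min(names(memb)[memb == b]),
                     character(1))
    big <- big[order(firsts)][1]
  }
  in_comp <- names(memb)[memb == as.integer(big)]
  e <- e[e$tf %in% in_comp & e$gene %in% in_comp, , drop = FALSE]
  nodes <- sub_nodes[sub_nodes$gene %in% in_comp, , drop = FALSE]
  prov <- net$provenance
  prov$component_counts <- c(n_tfs = sum(nodes$is_tf),
                             n_inflammation = sum(nodes$is_inflammation),
                             n_cancer = sum(nodes$is_cancer))
  regulatory_network(e, nodes = nodes, network_id = net$network_id,
                     phenotype = net$phenotype, provenance = prov)
}

#' Topology statistics of a connected regulatory network
#'
#' Reports the unweighted diameter, edge density, mean closeness over TF
#' nodes, mean shortest-path length over TF nodes, mean (unnormalised) node
#' betweenness over TF nodes, mean edge betweenness over all edges, and the
#' TF degree histogram.
#'
#' @param net a connected `regnet` (extract the component first).
#' @return a named list of statistics.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "regnet"))
  g <- .as_igraph(net)
  if (igraph::components(g)$no != 1L)
    stop("network is disconnected; run extract_ic_component() first")
  tf_ids <- net$nodes$gene[net$nodes$is_tf]
  D <- igraph::distances(g, weights = NA)
  tf_rows <- rownames(D) %in% tf_ids
  mean_sp_tf <- mean(D[tf_rows, , drop = FALSE][
    D[tf_rows, , drop = FALSE] > 0])
  deg <- igraph::degree(g)
  list(diameter = igraph::diameter(g, weights = NA),
       density = igraph::edge_density(g),
       mean_closeness_tf = mean(igraph::closeness(g, weights = NA,
                                                  normalized = FALSE)[tf_rows]),
       mean_shortest_path_tf = mean_sp_tf,
       mean_betweenness_tf = mean(igraph::betweenness(g, weights = NA)[tf_rows]),
       mean_edge_betweenness = mean(igraph::edge_betweenness(g, weights = NA)),
       tf_degree_histogram = table(deg[names(deg) %in% tf_ids]))
}
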