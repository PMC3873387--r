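# Differential regulation between an inflammation network/dataset and a
# cancer network/dataset: candidate TF-gene relationships from the combined
# neighborhoods of common TFs, MI differences recomputed from the raw
# expression of each condition, a pooled permutation null, FDR control, and
# intersection across network pairs into a dysregulated network.

#' Candidate TF-gene relationships for a network pair
#'
#' For every TF present in both networks, the union of its neighbor sets
#' across the two networks, returned as (tf, gene) pairs. A TF-TF relation
#' generated from both sides is counted once, anchored at the
#' lexicographically smaller common TF.
#'
#' @param net_i inflammation-condition `regnet`.
#' @param net_c cancer-condition `regnet`.
#' @return data.frame with columns `tf`, `gene`.
#' @export
candidate_relationships <- function(net_i, net_c) {
  na <- .tf_neighbor_sets(net_i)
  nb <- .tf_neighbor_sets(net_c)
  common <- intersect(names(na), names(nb))
  if (length(common) == 0L) stop("no common TFs between the two networks")
  pairs <- do.call(rbind, lapply(common, function(t) {
    nbs <- union(na[[t]], nb[[t]])
    if (length(nbs) == 0L) return(NULL)
    data.frame(tf = t, gene = nbs, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) stop("common TFs have no neighbors in either network")
  # TF-TF pair generated by both common TFs: anchor at the smaller id
  both <- pairs$gene %in% common
  flip <- both & pairs$gene < pairs$tf
  tmp <- pairs$tf[flip]
  pairs$tf[flip] <- pairs$gene[flip]
  pairs$gene[flip] <- tmp
  pairs <- pairs[!duplicated(pairs[c("tf", "gene")]), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' MI difference of candidate relationships between two conditions
#'
#' Both MI values are recomputed from the raw expression vectors of each
#' dataset with the package estimator, whether or not the edge survived
#' thresholding or DPI pruning in that condition's network, and
#' `delta_mi = mi_cancer - mi_inflammation`. Pairs with a gene missing from
#' either dataset are dropped with a message.
#'
#' @param pairs data.frame with columns `tf`, `gene` (from
#'   [candidate_relationships()]).
#' @param data_i,data_c [expression_dataset()] objects for the inflammation
#'   and cancer conditions.
#' @return data.frame `tf`, `gene`, `mi_inflammation`, `mi_cancer`,
#'   `delta_mi`.
#' @export
delta_mi <- function(pairs, data_i, data_c) {
  stopifnot(is.data.frame(pairs), all(c("tf", "gene") %in% names(pairs)))
  ok <- pairs$tf %in% data_i$genes & pairs$gene %in% data_i$genes &
    pairs$tf %in% data_c$genes & pairs$gene %in% data_c$genes
  if (any(!ok))
    message(sum(!ok), " pair(s) dropped: gene absent from one dataset")
  pairs <- pairs[ok, , drop = FALSE]
  ki <- .kernel_list(data_i$values)
  kc <- .kernel_list(data_c$values)
  ixi <- stats::setNames(seq_along(data_i$genes), data_i$genes)
  ixc <- stats::setNames(seq_along(data_c$genes), data_c$genes)
  mi_i <- .mi_pairs(ki, ixi[pairs$tf], ixi[pairs$gene],
                    length(data_i$samples))
  mi_c <- .mi_pairs(kc, ixc[pairs$tf], ixc[pairs$gene],
                    length(data_c$samples))
  data.frame(tf = pairs$tf, gene = pairs$gene,
             mi_inflammation = mi_i, mi_cancer = mi_c,
             delta_mi = mi_c - mi_i, stringsAsFactors = FALSE)
}

#' Pooled permutation null of MI differences
#'
#' For each of `n_perm` rounds a random pair of pseudo-condition datasets is
#' generated and the MI difference of every candidate relationship is
#' recomputed from them; all rounds are pooled into one empirical null
#' distribution. Two randomisation schemes are available:
#'
#' * `"label"` (default): the samples of the two datasets are pooled and
#'   randomly reassigned to two pseudo-conditions of the original sizes.
#'   This preserves the gene-gene dependence of the pooled data while
#'   destroying any condition difference, so the null carries the
#'   estimator's sampling variability at the observed dependence strengths
#'   and empirical p-values are calibrated under a global null.
#' * `"per-gene"`: each gene's values are independently permuted across
#'   samples within each dataset, destroying all gene-gene dependence while
#'   preserving marginals. This null is much narrower (both random MI values
#'   sit near zero) and is anticonservative for relationships with strong
#'   dependence in both conditions; it is retained for comparison.
#'
#' @param pairs data.frame with columns `tf`, `gene`.
#' @param data_i,data_c the two condition datasets (gene sets must cover
#'   the pairs; pairs with missing genes are dropped as in [delta_mi()]).
#' @param n_perm number of permutation rounds (default 100).
#' @param seed integer seed; deterministic given the seed.
#' @param method randomisation scheme, `"label"` or `"per-gene"`.
#' @return numeric vector of pooled null deltas
#'   (length `n_perm * nrow(pairs)` for pairs present in both datasets).
#' @export
permutation_null <- function(pairs, data_i, data_c, n_perm = 100L,
                             seed = 1L, method = c("label", "per-gene")) {
  stopifnot(n_perm >= 1L)
  method <- match.arg(method)
  ok <- pairs$tf %in% data_i$genes & pairs$gene %in% data_i$genes &
    pairs$tf %in% data_c$genes & pairs$gene %in% data_c$genes
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no candidate pairs present in both datasets")
  ni <- length(data_i$samples)
  nc <- length(data_c$samples)
  if (method == "label") {
    genes <- unique(c(pairs$tf, pairs$gene))
    X <- cbind(data_i$values[genes, , drop = FALSE],
               data_c$values[genes, , drop = FALSE])
    ix <- stats::setNames(seq_along(genes), genes)
    .with_seed(seed, {
      unlist(lapply(seq_len(n_perm), function(r) {
        shuffle <- sample.int(ni + nc)
        ki <- .kernel_list(X[, shuffle[seq_len(ni)], drop = FALSE])
        kc <- .kernel_list(X[, shuffle[-seq_len(ni)], drop = FALSE])
        .mi_pairs(kc, ix[pairs$tf], ix[pairs$gene], nc) -
          .mi_pairs(ki, ix[pairs$tf], ix[pairs$gene], ni)
      }), use.names = FALSE)
    })
  } else {
    ki <- .kernel_list(data_i$values)
    kc <- .kernel_list(data_c$values)
    ixi <- stats::setNames(seq_along(data_i$genes), data_i$genes)
    ixc <- stats::setNames(seq_along(data_c$genes), data_c$genes)
    genes_needed_i <- unique(c(ixi[pairs$tf], ixi[pairs$gene]))
    genes_needed_c <- unique(c(ixc[pairs$tf], ixc[pairs$gene]))
    .with_seed(seed, {
      unlist(lapply(seq_len(n_perm), function(r) {
        pi <- lapply(stats::setNames(genes_needed_i, genes_needed_i),
                     function(g) sample.int(ni))
        pc <- lapply(stats::setNames(genes_needed_c, genes_needed_c),
                     function(g) sample.int(nc))
        di <- .null_deltas(ki, ixi[pairs$tf], ixi[pairs$gene], pi, ni)
        dc <- .null_deltas(kc, ixc[pairs$tf], ixc[pairs$gene], pc, nc)
        dc - di
      }), use.names = FALSE)
    })
  }
}

# MI of pairs under per-gene column permutations of the kernel matrices
.null_deltas <- function(klist, ii, jj, perms, n) {
  plug <- vapply(seq_along(ii), function(k) {
    A <- klist[[ii[k]]]
    B <- klist[[jj[k]]]
    if (is.null(A) || is.null(B)) return(NA_real_)
    .mi_plugin(A[, perms[[as.character(ii[k])]], drop = FALSE],
               B[, perms[[as.character(jj[k])]], drop = FALSE])
  }, numeric(1))
  out <- .mi_correct(plug, n)
  out[is.na(plug)] <- 0
  out
}

#' Test candidate relationships against the permutation null
#'
#' Two-sided empirical p-values with the add-one convention,
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + length(null))`, followed by
#' Benjamini-Hochberg FDR across all tested pairs; relationships with
#' `q_fdr < fdr_cutoff` are returned as dysregulated, with direction `gain`
#' when `delta_mi > 0` and `loss` otherwise.
#'
#' @param deltas data.frame from [delta_mi()].
#' @param null numeric vector from [permutation_null()].
#' @param fdr_cutoff FDR significance cutoff (default 0.05).
#' @return data.frame of significant relationships (columns of `deltas`
#'   plus `p_empirical`, `q_fdr`, `direction`); the full tested table is
#'   attached as attribute `"all"`.
#' @export
test_dysregulation <- function(deltas, null, fdr_cutoff = 0.05) {
  stopifnot(is.data.frame(deltas), length(null) > 0L)
  sn <- sort(abs(null))
  N <- length(sn)
  # count of null |delta| >= observed |delta| via binary search
  geq <- N - findInterval(abs(deltas$delta_mi) - 1e-12, sn)
  deltas$p_empirical <- (1 + geq) / (1 + N)
  deltas$q_fdr <- stats::p.adjust(deltas$p_empirical, method = "BH")
  deltas$direction <- ifelse(deltas$delta_mi > 0, "gain", "loss")
  out <- deltas[deltas$q_fdr < fdr_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- deltas
  out
}

#' Intersect per-pair dysregulated relationships and build the network
#'
#' The final edge set is the intersection, over the supplied per-pair
#' significant lists, of (tf, gene) identities ("dysregulated
#' simultaneously" in every combination). The intersection is built into a
#' graph and reduced to its largest connected component. Per-list MI,
#' delta, and q values are retained with a `.k` suffix per contributing
#' pair.
#'
#' @param edge_lists list (length >= 1) of data.frames from
#'   [test_dysregulation()], one per (inflammation, cancer) network pair.
#' @param gs a [gene_sets()] object used for node role flags.
#' @param source_pairs optional character vector naming the contributing
#'   pairs.
#' @return object of class `dysnet`: fields `edges`, `nodes`,
#'   `source_pairs`, `component_stats`.
#' @export
intersect_and_build <- function(edge_lists, gs, source_pairs = NULL) {
  stopifnot(is.list(edge_lists), length(edge_lists) >= 1L,
            inherits(gs, "gene_sets"))
  keys <- lapply(edge_lists, function(e) paste(e$tf, e$gene, sep = "\r"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L)
    stop("empty intersection of dysregulated relationships (list sizes: ",
         paste(vapply(edge_lists, nrow, integer(1)), collapse = ", "), ")")
  base <- edge_lists[[1]][match(shared, keys[[1]]), c("tf", "gene")]
  for (k in seq_along(edge_lists)) {
    cols <- edge_lists[[k]][match(shared, keys[[k]]),
                            c("mi_inflammation", "mi_cancer", "delta_mi",
                              "q_fdr", "direction")]
    names(cols) <- paste0(names(cols), ".", k)
    base <- cbind(base, cols)
  }
  # convenience single-pair columns from the first contributing pair
  base$mi_inflammation <- base$mi_inflammation.1
  base$mi_cancer <- base$mi_cancer.1
  base$delta_mi <- base$delta_mi.1
  base$direction <- base$direction.1
  g <- igraph::graph_from_data_frame(base[c("tf", "gene")], directed = FALSE)
  memb <- igraph::components(g)$membership
  sizes <- table(memb)
  big <- names(sizes)[sizes == max(sizes)]
  if (length(big) > 1L) {
    firsts <- vapply(big, function(b) min(names(memb)[memb == b]),
                     character(1))
    big <- big[order(firsts)][1]
  }
  in_comp <- names(memb)[memb == as.integer(big)]
  edges <- base[base$tf %in% in_comp & base$gene %in% in_comp, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$tf, edges$gene)))
  nodes <- data.frame(gene = ids,
                      is_tf = ids %in% gs$tf_set,
                      is_inflammation = ids %in% gs$inflammation_set,
                      is_cancer = ids %in% gs$cancer_set,
                      stringsAsFactors = FALSE)
  # both counting conventions: by role flag (dual-annotated genes count in
  # each category) and exclusive (each node once, TF taking precedence)
  stats <- list(
    n_nodes = nrow(nodes),
    n_tfs = sum(nodes$is_tf),
    n_inflammation = sum(nodes$is_inflammation),
    n_cancer = sum(nodes$is_cancer),
    n_inflammation_only = sum(nodes$is_inflammation & !nodes$is_tf &
                                !nodes$is_cancer),
    n_cancer_only = sum(nodes$is_cancer & !nodes$is_tf &
                          !nodes$is_inflammation),
    n_dual_ic = sum(nodes$is_inflammation & nodes$is_cancer & !nodes$is_tf),
    n_edges = nrow(edges))
  structure(list(edges = edges, nodes = nodes,
                 source_pairs = source_pairs %||%
                   paste0("pair", seq_along(edge_lists)),
                 component_stats = stats),
            class = "dysnet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dysnet <- function(x, ...) {
  s <- x$component_stats
  cat(sprintf(
    "<dysnet> %d nodes (%d TFs, %d inflammation, %d cancer), %d edges\n",
    s$n_nodes, s$n_tfs, s$n_inflammation, s$n_cancer, s$n_edges))
  invisible(x)
}

# dysnet -> igraph
.dysnet_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[c("tf", "gene")],
                                directed = FALSE, vertices = net$nodes$gene)
}

#' Topology of a dysregulated network
#'
#' Average shortest path length, degree histogram, and a power-law fit of
#' the degree distribution: least squares of `log10 p(k)` on `log10 k` over
#' non-empty degree bins, reporting the exponent `gamma` (minus the slope)
#' and the fit's R squared. With fewer than 3 distinct degrees the exponent
#' is undefined (NA).
#'
#' @param net a connected `dysnet` (or `regnet`).
#' @return named list: `average_shortest_path`, `degree_histogram`,
#'   `gamma`, `r_squared`.
#' @export
dysregulated_topology <- function(net) {
  g <- if (inherits(net, "dysnet")) .dysnet_igraph(net) else .as_igraph(net)
  if (igraph::components(g)$no != 1L)
    stop("network is disconnected; extract the largest component first")
  deg <- igraph::degree(g)
  tab <- table(deg)
  fit <- .powerlaw_fit(as.numeric(names(tab)), as.numeric(tab) / sum(tab))
  list(average_shortest_path = igraph::mean_distance(g, directed = FALSE),
       degree_histogram = tab,
       gamma = fit$gamma, r_squared = fit$r_squared)
}

# least-squares power-law fit of a degree distribution on log-log scale;
# zero-count bins must already be absent; needs >= 3 distinct degrees
.powerlaw_fit <- function(k, pk) {
  keep <- pk > 0
  k <- k[keep]
  pk <- pk[keep]
  if (length(k) < 3L) return(list(gamma = NA_real_, r_squared = NA_real_))
  m <- stats::lm(log10(pk) ~ log10(k))
  # an exactly linear log-log histogram triggers summary.lm's perfect-fit
  # warning; that input is legitimate here
  list(gamma = -unname(stats::coef(m)[2]),
       r_squared = suppressWarnings(summary(m)$r.squared))
}

#' Export a dysregulated network for Cytoscape
#'
#' Same layout as [write_network_sif()]: SIF plus edge/node attribute TSVs.
#'
#' @param net a `dysnet`.
#' @param path SIF path.
#' @export
write_dysnet_sif <- function(net, path) {
  stopifnot(inherits(net, "dysnet"))
  rn <- regulatory_network(net$edges, nodes = net$nodes,
                           network_id = "dysregulated",
                           phenotype = "dysregulated")
  write_network_sif(rn, path)
}
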