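# Network-level topological overlap: similarity between two regulatory
# networks via the shared neighborhoods of their common TFs, hierarchical
# clustering of a network collection, and leave-k-out branch stability.
#
# The per-TF overlap formula is a set generalisation of the topological
# overlap measure: |N1 intersect N2| / min(|N1|, |N2|), with 0 for an empty
# neighborhood. Consequence (documented and tested): a neighborhood fully
# contained in the other scores 1 even when their sizes differ.

# named list of neighbor sets for every TF node of a network
.tf_neighbor_sets <- function(net) {
  tfs <- net$nodes$gene[net$nodes$is_tf]
  e <- net$edges
  nb <- lapply(tfs, function(t)
    unique(c(e$gene[e$tf == t], e$tf[e$gene == t])))
  stats::setNames(nb, tfs)
}

#' Per-TF topological overlap between two neighborhoods
#'
#' `|N1 intersect N2| / min(|N1|, |N2|)`; 0 when either set is empty.
#'
#' @param neighbors_1,neighbors_2 character vectors: the neighbor sets of
#'   one TF in two networks.
#' @return a number in `[0, 1]`.
#' @export
tf_tom <- function(neighbors_1, neighbors_2) {
  n1 <- unique(neighbors_1)
  n2 <- unique(neighbors_2)
  if (length(n1) == 0L || length(n2) == 0L) return(0)
  length(intersect(n1, n2)) / min(length(n1), length(n2))
}

#' Network topological overlap between two regulatory networks
#'
#' The sum, over all TFs present in both networks, of the per-TF
#' topological overlap of their neighbor sets ([tf_tom()]). Symmetric in
#' its arguments; returns 0 with a warning when the networks share no TF.
#'
#' @param net_a,net_b `regnet` objects.
#' @return a non-negative number.
#' @export
network_tom <- function(net_a, net_b) {
  na <- .tf_neighbor_sets(net_a)
  nb <- .tf_neighbor_sets(net_b)
  common <- intersect(names(na), names(nb))
  if (length(common) == 0L) {
    warning("no common TFs between '", net_a$network_id, "' and '",
            net_b$network_id, "'; network TOM = 0")
    return(0)
  }
  sum(vapply(common, function(t) tf_tom(na[[t]], nb[[t]]), numeric(1)))
}

# raw pairwise network-TOM matrix (including self values on the diagonal)
.raw_tom_matrix <- function(nets) {
  ids <- vapply(nets, function(n) n$network_id, character(1))
  nbs <- lapply(nets, .tf_neighbor_sets)
  m <- length(nets)
  raw <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in i:m) {
      common <- intersect(names(nbs[[i]]), names(nbs[[j]]))
      v <- if (length(common)) {
        sum(vapply(common, function(t) tf_tom(nbs[[i]][[t]], nbs[[j]][[t]]),
                   numeric(1)))
      } else 0
      raw[i, j] <- raw[j, i] <- v
    }
  }
  raw
}

# normalize a raw TOM matrix by its largest off-diagonal value
.normalize_tom <- function(raw) {
  off <- raw
  diag(off) <- NA
  const <- max(off, na.rm = TRUE)
  if (!is.finite(const) || const == 0)
    stop("all pairwise network TOM values are zero: the networks share no ",
         "common regulatory structure")
  list(similarity = raw / const, constant = const)
}

#' Pairwise network-TOM similarity matrix
#'
#' Fills the raw network-TOM matrix for all pairs, then normalises by the
#' maximum over distinct pairs so the most similar pair has similarity
#' exactly 1. The diagonal (self-TOM / constant) is reported but excluded
#' from the normalisation and unused by the clustering.
#'
#' @param nets list of at least 3 `regnet` objects with distinct ids.
#' @return object of class `netsim` with fields `network_ids`, `raw_tom`,
#'   `similarity`, `normalization_constant`, and `phenotypes`.
#' @export
similarity_matrix <- function(nets) {
  if (length(nets) < 3L) stop("need at least 3 networks")
  ids <- vapply(nets, function(n) n$network_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate network ids")
  raw <- .raw_tom_matrix(nets)
  nrm <- .normalize_tom(raw)
  structure(list(network_ids = ids, raw_tom = raw,
                 similarity = nrm$similarity,
                 normalization_constant = nrm$constant,
                 phenotypes = stats::setNames(
                   vapply(nets, function(n) n$phenotype, character(1)), ids)),
            class = "netsim")
}

#' @export
print.netsim <- function(x, ...) {
  cat(sprintf("<netsim> %d networks, normalization constant %.4g\n",
              length(x$network_ids), x$normalization_constant))
  invisible(x)
}

#' Hierarchically cluster a network collection
#'
#' Agglomerative clustering with average linkage on distance
#' `1 - similarity`. Deterministic given the similarity matrix; leaves are
#' labelled by network id.
#'
#' @param sim a `netsim` from [similarity_matrix()].
#' @return an [stats::hclust] dendrogram.
#' @export
cluster_networks <- function(sim) {
  stopifnot(inherits(sim, "netsim"))
  d <- 1 - sim$similarity
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Write a network dendrogram as Newick text
#'
#' @param hc an [stats::hclust] from [cluster_networks()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

# all clades of an hclust as a list of leaf-id sets with merge heights;
# single leaves are included as trivial clades at height 0
.clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  out <- lapply(seq_len(n), function(i) list(leaves = hc$labels[i], height = 0))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) hc$labels[-x] else sets[[x]]
    sets[[k]] <- sort(c(pick(hc$merge[k, 1]), pick(hc$merge[k, 2])))
    out[[n + k]] <- list(leaves = sets[[k]], height = hc$height[k])
  }
  out
}

#' Find candidate inflammation-cancer bridge clades
#'
#' Returns the minimal dendrogram clades containing at least one
#' inflammation-phenotype leaf and at least one cancer-phenotype leaf
#' (i.e. mixed clades none of whose sub-clades is mixed), sorted by clade
#' height ascending. These are the candidate network pairs for the
#' dysregulation analysis.
#'
#' @param hc an [stats::hclust] with network-id labels.
#' @param phenotypes named character vector mapping every leaf label to its
#'   phenotype.
#' @param inflammation_labels,cancer_labels phenotype values counted as
#'   inflammation / cancer.
#' @return list of clades, each a list with `leaves` (ids) and `height`.
#' @export
find_bridge_candidates <- function(hc, phenotypes,
                                   inflammation_labels = c("UC", "CD", "IBD",
                                                           "inflammation"),
                                   cancer_labels = c("CRC", "Ca", "cancer")) {
  if (!all(hc$labels %in% names(phenotypes)))
    stop("every leaf needs a phenotype")
  is_mixed <- function(leaves) {
    ph <- phenotypes[leaves]
    any(ph %in% inflammation_labels) && any(ph %in% cancer_labels)
  }
  cl <- .clades(hc)
  mixed <- vapply(cl, function(x) is_mixed(x$leaves), logical(1))
  minimal <- vapply(seq_along(cl), function(i) {
    if (!mixed[i]) return(FALSE)
    # minimal: no strictly smaller mixed clade nested inside
    !any(vapply(seq_along(cl), function(j) {
      mixed[j] && length(cl[[j]]$leaves) < length(cl[[i]]$leaves) &&
        all(cl[[j]]$leaves %in% cl[[i]]$leaves)
    }, logical(1)))
  }, logical(1))
  res <- cl[minimal]
  res[order(vapply(res, `[[`, numeric(1), "height"))]
}

#' Branch recurrence under leave-one-out / leave-two-out perturbation
#'
#' For each removal set (all single networks for `leave_k = 1`; all pairs,
#' or a seeded random sample of at most `max_pairs` pairs, for
#' `leave_k = 2`), the remaining networks are reclustered (the raw pairwise
#' TOM values are reused; the normalisation constant is recomputed on the
#' surviving collection) and each named branch is checked for recurrence:
#' it recurs (cell 1) iff some dendrogram clade's leaf set equals the
#' branch minus the removed networks. A branch whose surviving member set
#' is empty gets NA (not applicable, distinct from 0).
#'
#' @param nets list of `regnet` objects.
#' @param branches named list of character vectors (network-id sets).
#' @param leave_k 1 or 2.
#' @param seed integer seed (used only when pair sampling kicks in).
#' @param max_pairs cap on the number of leave-2-out removals.
#' @return data.frame with one row per removal (`removed` column) and one
#'   0/1/NA column per branch.
#' @export
branch_recurrence <- function(nets, branches, leave_k = 1L, seed = 1L,
                              max_pairs = 500L) {
  stopifnot(leave_k %in% c(1L, 2L), is.list(branches),
            !is.null(names(branches)))
  ids <- vapply(nets, function(n) n$network_id, character(1))
  bad <- setdiff(unlist(branches), ids)
  if (length(bad))
    stop("branch members not in the collection: ", paste(bad, collapse = ", "))
  raw <- .raw_tom_matrix(nets)
  removals <- if (leave_k == 1L) {
    as.list(ids)
  } else {
    pairs <- utils::combn(ids, 2L, simplify = FALSE)
    if (length(pairs) > max_pairs)
      pairs <- .with_seed(seed, sample(pairs, max_pairs))
    pairs
  }
  rows <- lapply(removals, function(rm) {
    keep <- setdiff(ids, rm)
    nrm <- .normalize_tom(raw[keep, keep, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(1 - nrm$similarity),
                        method = "average")
    leafsets <- lapply(.clades(hc), `[[`, "leaves")
    vapply(branches, function(b) {
      surv <- sort(setdiff(b, rm))
      if (length(surv) == 0L) return(NA_real_)
      as.numeric(any(vapply(leafsets, identical, logical(1), y = surv)))
    }, numeric(1))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- names(branches)
  cbind(data.frame(removed = vapply(removals, paste, character(1),
                                    collapse = "+"),
                   stringsAsFactors = FALSE), out)
}
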