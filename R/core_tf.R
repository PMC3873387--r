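# Core-TF selection from a dysregulated network: degree plus
# inflammation/cancer composition-ratio thresholds, TF categorisation, and
# the core subnetwork export.

#' Score every TF of a dysregulated network
#'
#' For each TF node: its degree `k`, the numbers of adjacent inflammation
#' and cancer genes (a neighbor annotated in both sets increments both
#' counts), the composition ratios `ratio_inflammation = n_inflammation / k`
#' and `ratio_cancer = n_cancer / k`, the category (see
#' [categorize_tfs()]), and the core flag (see [select_core()]).
#'
#' @param net a `dysnet` (or `regnet`).
#' @param gs a [gene_sets()] object (used for neighbor role flags; the
#'   network's own node table is used when present).
#' @param degree_min,ratio_min thresholds for the core flag (defaults 8 and 0.1).
#' @return data.frame of class `core_tf_report` with one row per TF:
#'   `tf`, `degree`, `n_adjacent_inflammation`, `n_adjacent_cancer`,
#'   `ratio_inflammation`, `ratio_cancer`, `category`, `is_core`.
#' @export
score_tfs <- function(net, gs, degree_min = 8L, ratio_min = 0.1) {
  stopifnot(inherits(net, "dysnet") || inherits(net, "regnet"),
            inherits(gs, "gene_sets"))
  nodes <- net$nodes
  e <- net$edges
  tfs <- nodes$gene[nodes$is_tf]
  is_infl <- stats::setNames(nodes$is_inflammation, nodes$gene)
  is_canc <- stats::setNames(nodes$is_cancer, nodes$gene)
  rows <- lapply(tfs, function(t) {
    nbs <- unique(c(e$gene[e$tf == t], e$tf[e$gene == t]))
    k <- length(nbs)
    if (k == 0L) return(NULL)
    nI <- sum(is_infl[nbs])
    nC <- sum(is_canc[nbs])
    data.frame(tf = t, degree = k,
               n_adjacent_inflammation = nI, n_adjacent_cancer = nC,
               ratio_inflammation = nI / k, ratio_cancer = nC / k,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (is.null(rep))
    rep <- data.frame(tf = character(0), degree = integer(0),
                      n_adjacent_inflammation = integer(0),
                      n_adjacent_cancer = integer(0),
                      ratio_inflammation = numeric(0),
                      ratio_cancer = numeric(0))
  rownames(rep) <- NULL
  class(rep) <- c("core_tf_report", "data.frame")
  rep <- categorize_tfs(rep, ratio_min = ratio_min)
  rep$is_core <- rep$degree >= degree_min &
    rep$ratio_inflammation >= ratio_min & rep$ratio_cancer >= ratio_min
  rep
}

#' Categorise TFs by the composition of their neighbors
#'
#' `cancerogenic` when the cancer ratio exceeds 0.5 and the inflammation
#' ratio is below `ratio_min`; `inflammatory` symmetrically;
#' `IC-specific` when both ratios reach `ratio_min`; `other` otherwise
#' ("mostly adjacent" is operationalised as a ratio above 0.5 with the
#' other ratio below `ratio_min`).
#'
#' @param report a `core_tf_report` from [score_tfs()].
#' @param ratio_min the composition-ratio threshold (default 0.1).
#' @return the report with its `category` column (re)computed.
#' @export
categorize_tfs <- function(report, ratio_min = 0.1) {
  rI <- report$ratio_inflammation
  rC <- report$ratio_cancer
  report$category <- ifelse(
    rC > 0.5 & rI < ratio_min, "cancerogenic",
    ifelse(rI > 0.5 & rC < ratio_min, "inflammatory",
           ifelse(rI >= ratio_min & rC >= ratio_min, "IC-specific", "other")))
  report
}

#' Select core TFs
#'
#' A TF is core when its degree is at least `degree_min` and both
#' composition ratios are at least `ratio_min`. Results are sorted by
#' degree descending, then by TF id.
#'
#' @param report a `core_tf_report` from [score_tfs()].
#' @param degree_min minimum degree (default 8).
#' @param ratio_min minimum inflammation and cancer composition ratios
#'   (default 0.1).
#' @return character vector of core TF ids.
#' @export
select_core <- function(report, degree_min = 8L, ratio_min = 0.1) {
  stopifnot(degree_min >= 0, ratio_min >= 0)
  sel <- report[report$degree >= degree_min &
                  report$ratio_inflammation >= ratio_min &
                  report$ratio_cancer >= ratio_min, , drop = FALSE]
  sel$tf[order(-sel$degree, sel$tf)]
}

#' Core subnetwork: core TFs plus their direct neighbors
#'
#' Induced on the core TFs and every gene directly connected to one,
#' keeping only edges incident to a core TF.
#'
#' @param net a `dysnet`.
#' @param core_ids non-empty character vector of TF ids (subset of the
#'   network's TF nodes).
#' @return a `dysnet` restricted to the core subnetwork (its
#'   `component_stats` recomputed; may be disconnected if the cores do not
#'   share neighbors).
#' @export
core_subnetwork <- function(net, core_ids) {
  stopifnot(inherits(net, "dysnet"))
  if (length(core_ids) == 0L) stop("core_ids is empty")
  tf_nodes <- net$nodes$gene[net$nodes$is_tf]
  bad <- setdiff(core_ids, tf_nodes)
  if (length(bad))
    stop("not TF nodes of the network: ", paste(bad, collapse = ", "))
  e <- net$edges
  keep <- e$tf %in% core_ids | e$gene %in% core_ids
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  ids <- sort(unique(c(e$tf, e$gene)))
  nodes <- net$nodes[net$nodes$gene %in% ids, , drop = FALSE]
  rownames(nodes) <- NULL
  stats <- list(n_nodes = nrow(nodes), n_tfs = sum(nodes$is_tf),
                n_inflammation = sum(nodes$is_inflammation),
                n_cancer = sum(nodes$is_cancer),
                n_inflammation_only = sum(nodes$is_inflammation &
                                            !nodes$is_tf & !nodes$is_cancer),
                n_cancer_only = sum(nodes$is_cancer & !nodes$is_tf &
                                      !nodes$is_inflammation),
                n_dual_ic = sum(nodes$is_inflammation & nodes$is_cancer &
                                  !nodes$is_tf),
                n_edges = nrow(e))
  structure(list(edges = e, nodes = nodes, source_pairs = net$source_pairs,
                 component_stats = stats),
            class = "dysnet")
}
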