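# Differential-expression baseline: a SAM-style moderated t statistic with
# permutation p-values. Its role in the pipeline is the contrast with the
# network approach: a dependence-only change between conditions (couplings
# rewired, marginal moments preserved) is invisible to per-gene DE while
# being exactly what the dysregulation module detects.

#' SAM-style differential expression between two conditions
#'
#' For every common gene, the moderated t statistic
#' `t = (mean_c - mean_i) / (s + s0)` where `s` is the pooled standard
#' error and the fudge factor `s0` is the median of the `s` values (keeping
#' `t` finite for genes with tiny variance). P-values come from permuting
#' the condition labels `n_perm` times and pooling the permuted statistics
#' across genes (two-sided, add-one); q-values by Benjamini-Hochberg.
#'
#' @param data_i,data_c [expression_dataset()] objects (>= 2 samples each).
#' @param fdr significance cutoff on the BH q-value (default 0.1, the
#'   loose threshold used for this baseline).
#' @param n_perm number of label permutations (default 200).
#' @param seed integer seed.
#' @return data.frame of class `de_result`: `gene`, `effect` (difference of
#'   means, log2 units), `t_statistic`, `p`, `q_fdr`, `significant`.
#' @export
differential_genes <- function(data_i, data_c, fdr = 0.1, n_perm = 200L,
                               seed = 1L) {
  stopifnot(inherits(data_i, "expression_dataset"),
            inherits(data_c, "expression_dataset"))
  common <- intersect(data_i$genes, data_c$genes)
  if (length(common) == 0L) stop("no common genes")
  ni <- length(data_i$samples)
  nc <- length(data_c$samples)
  if (ni < 2L || nc < 2L) stop("each condition needs at least 2 samples")
  X <- cbind(data_i$values[common, , drop = FALSE],
             data_c$values[common, , drop = FALSE])
  labels_c <- c(rep(FALSE, ni), rep(TRUE, nc))
  mod_t <- function(lab) {
    xi <- X[, !lab, drop = FALSE]
    xc <- X[, lab, drop = FALSE]
    mi <- rowMeans(xi)
    mc <- rowMeans(xc)
    vp <- ((ni - 1) * apply(xi, 1, stats::var) +
             (nc - 1) * apply(xc, 1, stats::var)) / (ni + nc - 2)
    s <- sqrt(vp * (1 / ni + 1 / nc))
    s0 <- stats::median(s)
    list(effect = mc - mi, t = (mc - mi) / (s + s0))
  }
  obs <- mod_t(labels_c)
  null_t <- .with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(r) {
      mod_t(sample(labels_c))$t
    }), use.names = FALSE)
  })
  sn <- sort(abs(null_t))
  N <- length(sn)
  geq <- N - findInterval(abs(obs$t) - 1e-12, sn)
  p <- (1 + geq) / (1 + N)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = common, effect = obs$effect,
                    t_statistic = obs$t, p = p, q_fdr = q,
                    significant = q < fdr, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Overlap between differential genes and core TFs
#'
#' @param de a `de_result` from [differential_genes()].
#' @param core_ids character vector of core TF ids.
#' @return list with `n_overlap`, `overlap`, `de_genes`, `core_tfs`.
#' @export
overlap_with_core <- function(de, core_ids) {
  sig <- de$gene[de$significant]
  shared <- intersect(sig, core_ids)
  list(n_overlap = length(shared), overlap = shared,
       de_genes = sig, core_tfs = core_ids)
}
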