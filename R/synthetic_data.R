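# Linear-Gaussian synthetic data with planted condition-specific regulatory
# structure. The generative model is deliberately simple: for a planted edge
# TF -> target with coupling beta, target = beta * TF + noise, so mutual
# information has the closed form -0.5 * log(1 - rho^2) with
# rho = beta / sqrt(beta^2 + noise_sd^2), giving an analytic oracle for the
# whole inference stack. Marginal means and variances are identical across
# conditions by construction, so condition differences live purely in the
# dependence structure.

.condition_names <- function(n) {
  base <- c("inflammation", "cancer", "normal", "bridge")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("condition", seq(length(base) + 1L, n)))
}

# deterministic 31-bit string hash (per-dataset seed derivation)
.string_seed <- function(seed, id) {
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(id)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' Generate a planted regulatory model
#'
#' Builds a ground-truth model over `n_tfs` transcription factors and
#' `n_targets` target genes. A fraction `frac_shared_edges` of targets form
#' a backbone regulated identically in every condition; the remaining
#' targets get an independently drawn condition-private regulator. A
#' fraction `frac_dysregulated` of targets are "dysregulated" between the
#' `inflammation` and `cancer` conditions: their coupling flips between
#' `beta` and 0 (half losses, half gains), and these edges are concentrated
#' on a small set of bridge TFs (about `dys_per_tf` targets each, balanced
#' across the inflammation and cancer gene sets) so that bridge regulators
#' are recoverable by degree-based core-TF selection. A low density of
#' TF-TF edges (shared across conditions) is also planted. The gene sets
#' assign half the targets to the inflammation set and half to the cancer
#' set, plus a small planted overlap annotated in both.
#'
#' @param n_tfs,n_targets counts (>= 1).
#' @param n_conditions number of conditions; the first four are named
#'   `inflammation`, `cancer`, `normal`, `bridge`.
#' @param frac_shared_edges fraction of targets on the shared backbone.
#' @param frac_dysregulated fraction of targets dysregulated between the
#'   inflammation and cancer conditions.
#' @param seed integer seed; the model is deterministic given the seed.
#' @param beta coupling strength of planted edges, in (0, 1].
#' @param noise_sd target noise standard deviation.
#' @param dys_per_tf target number of dysregulated edges per bridge TF.
#' @param tf_tf_density probability that a TF is itself regulated by an
#'   earlier TF.
#' @param frac_dual_parent fraction of backbone/private targets given a
#'   second TF regulator; shared targets connect the TFs through common
#'   neighborhoods so inferred networks have a giant connected component,
#'   as regulatory networks do.
#' @param frac_set_overlap fraction of targets annotated in both IC sets.
#' @param tf_weights optional sampling weights (length `n_tfs`) for target
#'   regulator assignment; skewed weights plant hub TFs and a right-skewed
#'   degree distribution.
#' @return an object of class `planted_model` with fields
#'   `edges_by_condition` (per-condition data.frames `tf`, `gene`, `beta`),
#'   `gene_sets`, `dysregulated` (ground-truth table with per-condition
#'   couplings and gain/loss direction), `bridge_tfs`, `conditions`,
#'   `beta`, `noise_sd`, `seed`.
#' @export
generate_model <- function(n_tfs, n_targets, n_conditions = 3L,
                           frac_shared_edges = 0.7, frac_dysregulated = 0.1,
                           seed = 1L, beta = 0.9, noise_sd = 0.3,
                           dys_per_tf = 10L, tf_tf_density = 0.1,
                           frac_dual_parent = 0.3, frac_set_overlap = 0.02,
                           tf_weights = NULL) {
  stopifnot(n_tfs >= 1, n_targets >= 1, n_conditions >= 1,
            frac_shared_edges >= 0, frac_shared_edges <= 1,
            frac_dysregulated >= 0, frac_dysregulated <= 1,
            beta > 0, beta <= 1, noise_sd > 0)
  conditions <- .condition_names(n_conditions)
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  target_ids <- sprintf("G%04d", seq_len(n_targets))
  n_dys <- round(frac_dysregulated * n_targets)
  n_shared <- round(frac_shared_edges * n_targets)
  if (n_dys + n_shared > n_targets)
    stop("infeasible fractions: frac_shared_edges + frac_dysregulated ",
         "exceed the available targets")
  if (n_dys > 0 && !all(c("inflammation", "cancer") %in% conditions))
    stop("dysregulation requires both the inflammation and cancer conditions")
  .with_seed(seed, {
    targets <- sample(target_ids)
    dys_targets <- targets[seq_len(n_dys)]
    shared_targets <- targets[seq_len(n_shared) + n_dys]
    private_targets <- setdiff(targets, c(dys_targets, shared_targets))
    # bridge TFs concentrate the dysregulated edges
    n_bridge <- if (n_dys > 0) max(1L, ceiling(n_dys / dys_per_tf)) else 0L
    bridge_tfs <- if (n_bridge > 0) sort(sample(tf_ids, n_bridge)) else
      character(0)
    dys <- if (n_dys > 0) {
      p <- seq_len(n_dys)
      # round-robin over bridge TFs; gain/loss alternates per round so every
      # bridge TF gets both directions whatever the TF count's parity
      loss <- (floor((p - 1L) / n_bridge) %% 2L) == 0L
      data.frame(tf = bridge_tfs[(p - 1L) %% n_bridge + 1L],
                 gene = dys_targets,
                 beta_inflammation = ifelse(loss, beta, 0),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(tf = character(0), gene = character(0),
                 beta_inflammation = numeric(0))
    }
    dys$beta_cancer <- ifelse(dys$beta_inflammation > 0, 0, beta)
    dys$direction <- ifelse(dys$beta_cancer > dys$beta_inflammation,
                            "gain", "loss")
    dys_primary <- dys
    if (n_dys > 0 && n_bridge >= 2L) {
      # dysregulated TF-TF edges chain consecutive bridge TFs so the
      # dysregulated edges form one connected network rather than isolated
      # TF stars; as strong as the primary dysregulated couplings
      chain_loss <- seq_len(n_bridge - 1L) %% 2L == 1L
      chain <- data.frame(tf = bridge_tfs[-n_bridge],
                          gene = bridge_tfs[-1L],
                          beta_inflammation = ifelse(chain_loss, beta, 0),
                          stringsAsFactors = FALSE)
      chain$beta_cancer <- ifelse(chain$beta_inflammation > 0, 0, beta)
      chain$direction <- ifelse(chain$beta_cancer > chain$beta_inflammation,
                                "gain", "loss")
      dys <- rbind(dys, chain)
    }
    shared <- data.frame(tf = sample(tf_ids, n_shared, replace = TRUE,
                                     prob = tf_weights),
                         gene = shared_targets,
                         beta = rep(beta, n_shared), stringsAsFactors = FALSE)
    # a second, distinct regulator for a fraction of the backbone targets
    second_parent <- function(e) {
      if (n_tfs < 2L || frac_dual_parent <= 0 || nrow(e) == 0L) return(NULL)
      pick <- which(stats::runif(nrow(e)) < frac_dual_parent)
      if (length(pick) == 0L) return(NULL)
      data.frame(
        tf = vapply(e$tf[pick],
                    function(t) sample(setdiff(tf_ids, t), 1L), character(1)),
        gene = e$gene[pick], beta = beta, stringsAsFactors = FALSE)
    }
    shared <- rbind(shared, second_parent(shared))
    # TF-TF regulation at low density; parents always have a lower index;
    # bridge TFs are excluded as children (their regulation is the planted
    # dysregulated chain above)
    tf_parent <- which(stats::runif(n_tfs) < tf_tf_density &
                         seq_len(n_tfs) > 1 & !(tf_ids %in% bridge_tfs))
    tf_edges <- data.frame(
      tf = tf_ids[vapply(tf_parent, function(j) sample.int(j - 1L, 1L),
                         integer(1))],
      gene = tf_ids[tf_parent], beta = rep(beta, length(tf_parent)),
      stringsAsFactors = FALSE)
    edges_by_condition <- stats::setNames(lapply(conditions, function(cond) {
      private <- data.frame(
        tf = sample(tf_ids, length(private_targets), replace = TRUE,
                    prob = tf_weights),
        gene = private_targets, beta = rep(beta, length(private_targets)),
        stringsAsFactors = FALSE)
      private <- rbind(private, second_parent(private))
      b <- switch(cond, inflammation = dys$beta_inflammation,
                  cancer = dys$beta_cancer,
                  rep(beta, nrow(dys)))
      dys_cond <- data.frame(tf = dys$tf, gene = dys$gene, beta = b,
                             stringsAsFactors = FALSE)
      e <- rbind(shared, private, dys_cond[dys_cond$beta > 0, ], tf_edges)
      e[order(e$gene, e$tf), ]
    }), conditions)
    # gene sets: split targets between the two IC sets; dysregulated targets
    # alternate so bridge TFs touch both sets; small planted overlap
    half <- ceiling(length(targets) / 2)
    dys_infl <- if (n_dys > 0) {
      dys_primary$gene[
        (floor((seq_len(n_dys) - 1L) / max(n_bridge, 1L)) %% 2L) == 0L]
    } else character(0)
    infl <- c(dys_infl,
              setdiff(targets, dys_targets)[
                seq_len(max(half - length(dys_infl), 0L))])
    canc <- setdiff(targets, infl)
    n_ov <- round(frac_set_overlap * n_targets)
    if (n_ov > 0) {
      infl <- c(infl, sample(setdiff(canc, dys_targets),
                             min(n_ov, length(setdiff(canc, dys_targets)))))
    }
    structure(list(tf_ids = tf_ids, target_ids = target_ids,
                   conditions = conditions,
                   edges_by_condition = edges_by_condition,
                   gene_sets = gene_sets(tf_ids, infl, canc),
                   dysregulated = dys, bridge_tfs = bridge_tfs,
                   beta = beta, noise_sd = noise_sd, seed = seed),
              class = "planted_model")
  })
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf(
    "<planted_model> %d TFs, %d targets, conditions: %s; %d dysregulated edges on %d bridge TFs\n",
    length(x$tf_ids), length(x$target_ids),
    paste(x$conditions, collapse = ", "), nrow(x$dysregulated),
    length(x$bridge_tfs)))
  invisible(x)
}

#' Simulate one expression dataset from a planted model
#'
#' TF expression is drawn i.i.d. standard normal per sample (TFs regulated
#' by another TF follow the same linear rule as targets); each regulated
#' target is the sum of `beta * regulator` over its in-edges plus
#' `Normal(0, noise_sd)` noise; unregulated targets are pure noise with the
#' variance they would have when regulated, so marginal moments match
#' across conditions. Values are rescaled per gene to a log2-like range
#' (mean 8, sd 2).
#'
#' @param model a [generate_model()] result.
#' @param condition condition name present in the model.
#' @param n_samples number of samples (>= 1).
#' @param dataset_id identifier of the simulated dataset.
#' @param seed integer seed; deterministic given the seed.
#' @param phenotype phenotype label recorded on the dataset; defaults to
#'   the condition name (override to plant, e.g., a cancer-labelled dataset
#'   simulated from the bridge condition).
#' @return an [expression_dataset()].
#' @export
simulate_dataset <- function(model, condition, n_samples, dataset_id,
                             seed = 1L, phenotype = condition) {
  stopifnot(inherits(model, "planted_model"))
  if (!condition %in% model$conditions)
    stop("unknown condition '", condition, "'")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  edges <- model$edges_by_condition[[condition]]
  sigma <- model$noise_sd
  .with_seed(seed, {
    tf_mat <- matrix(stats::rnorm(length(model$tf_ids) * n_samples),
                     nrow = length(model$tf_ids),
                     dimnames = list(model$tf_ids, NULL))
    # TF-TF edges: recompute regulated TFs in index order (parents first)
    tf_e <- edges[edges$gene %in% model$tf_ids, , drop = FALSE]
    for (g in model$tf_ids) {
      pe <- tf_e[tf_e$gene == g, , drop = FALSE]
      if (nrow(pe)) {
        tf_mat[g, ] <- as.vector(pe$beta %*% tf_mat[pe$tf, , drop = FALSE]) +
          stats::rnorm(n_samples, sd = sigma)
      }
    }
    tgt_mat <- matrix(NA_real_, nrow = length(model$target_ids),
                      ncol = n_samples,
                      dimnames = list(model$target_ids, NULL))
    tg_e <- edges[edges$gene %in% model$target_ids, , drop = FALSE]
    nominal_sd <- sqrt(model$beta^2 + sigma^2)
    for (g in model$target_ids) {
      pe <- tg_e[tg_e$gene == g, , drop = FALSE]
      if (nrow(pe)) {
        raw <- as.vector(pe$beta %*% tf_mat[pe$tf, , drop = FALSE]) +
          stats::rnorm(n_samples, sd = sigma)
        tgt_mat[g, ] <- raw / sqrt(sum(pe$beta^2) + sigma^2)
      } else {
        # unregulated here (e.g. coupling planted to 0 in this condition):
        # pure noise with matched marginal variance
        tgt_mat[g, ] <- stats::rnorm(n_samples, sd = nominal_sd) / nominal_sd
      }
    }
    tf_sd <- ifelse(model$tf_ids %in% tf_e$gene, nominal_sd, 1)
    tf_mat <- tf_mat / tf_sd
    values <- 8 + 2 * rbind(tf_mat, tgt_mat)
    colnames(values) <- sprintf("%s_S%04d", dataset_id, seq_len(n_samples))
    expression_dataset(values, dataset_id = dataset_id,
                       phenotype = phenotype)
  })
}

#' Simulate a multi-dataset study
#'
#' One dataset per design row; each dataset's seed is derived
#' deterministically from the master seed and the dataset id, so the result
#' is invariant to the order of the design rows.
#'
#' @param model a [generate_model()] result.
#' @param design data.frame with columns `dataset_id`, `condition`,
#'   `n_samples`, and optionally `phenotype`.
#' @param seed master integer seed.
#' @return named list of [expression_dataset()] objects.
#' @export
simulate_study <- function(model, design, seed = 1L) {
  stopifnot(is.data.frame(design))
  if (nrow(design) == 0L) stop("empty design")
  if (anyDuplicated(design$dataset_id))
    stop("duplicate dataset_id in design")
  if (is.null(design$phenotype)) design$phenotype <- design$condition
  out <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    simulate_dataset(model, condition = d$condition,
                     n_samples = d$n_samples, dataset_id = d$dataset_id,
                     seed = .string_seed(seed, d$dataset_id),
                     phenotype = d$phenotype)
  })
  stats::setNames(out, design$dataset_id)
}

#' Population mutual information of gene pairs under a planted model
#'
#' In the linear-Gaussian generative model every gene is a linear
#' combination of independent unit factors (one intrinsic factor per gene),
#' so the population correlation of any gene pair — and hence its exact
#' mutual information `-0.5 * log(1 - rho^2)` — follows from the planted
#' coefficients. This is the ground-truth oracle for dependence between any
#' two genes, including indirect dependence transmitted through TF-TF
#' regulation, which the direct planted edge list does not enumerate.
#'
#' @param model a [generate_model()] result.
#' @param condition condition name in the model.
#' @param pairs data.frame with columns `tf`, `gene` (any gene pairs).
#' @return numeric vector: population MI (nats) per pair.
#' @export
model_population_mi <- function(model, condition, pairs) {
  stopifnot(inherits(model, "planted_model"))
  if (!condition %in% model$conditions)
    stop("unknown condition '", condition, "'")
  edges <- model$edges_by_condition[[condition]]
  ids <- c(model$tf_ids, model$target_ids)
  p <- length(ids)
  idx <- stats::setNames(seq_len(p), ids)
  sigma <- model$noise_sd
  L <- matrix(0, p, p)   # loadings of each gene on the unit factors
  regulated <- ids %in% edges$gene
  for (g in seq_len(p)) {
    if (!regulated[g]) {
      L[g, g] <- 1       # root TF or unregulated target: pure intrinsic
      next
    }
    pe <- edges[edges$gene == ids[g], , drop = FALSE]
    L[g, ] <- as.vector(pe$beta %*% L[idx[pe$tf], , drop = FALSE])
    L[g, g] <- L[g, g] + sigma
  }
  nrm <- sqrt(rowSums(L^2))
  rho <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- idx[[pairs$tf[k]]]
    j <- idx[[pairs$gene[k]]]
    sum(L[i, ] * L[j, ]) / (nrm[i] * nrm[j])
  }, numeric(1))
  -0.5 * log(pmax(1 - rho^2, 1e-12))
}

#' Write a simulated study to disk
#'
#' Writes one expression TSV per dataset, the three gene-set files (one
#' gene per line), and a ground-truth JSON (planted edges per condition,
#' dysregulated edges, bridge TFs).
#'
#' @param model a [generate_model()] result.
#' @param datasets list returned by [simulate_study()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
export_study <- function(model, datasets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(datasets, function(ds) {
    p <- file.path(dir, paste0(ds$dataset_id, ".tsv"))
    write_expression_matrix(ds, p)
    p
  }, character(1))
  gs <- model$gene_sets
  writeLines(gs$tf_set, file.path(dir, "tf_set.txt"))
  writeLines(gs$inflammation_set, file.path(dir, "inflammation_set.txt"))
  writeLines(gs$cancer_set, file.path(dir, "cancer_set.txt"))
  jsonlite::write_json(
    list(conditions = model$conditions,
         edges_by_condition = model$edges_by_condition,
         dysregulated = model$dysregulated,
         bridge_tfs = model$bridge_tfs,
         beta = model$beta, noise_sd = model$noise_sd, seed = model$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, c("tf_set.txt", "inflammation_set.txt",
                                      "cancer_set.txt",
                                      "ground_truth.json"))))
}
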