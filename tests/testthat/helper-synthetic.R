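# fixtures built in code: tiny gene sets, hand-made networks, and
# collections of planted networks for similarity/clustering tests

tiny_gs <- function(n_tfs = 5, n_infl = 10, n_canc = 10) {
  gene_sets(tf_set = sprintf("TF%03d", seq_len(n_tfs)),
            inflammation_set = sprintf("I%03d", seq_len(n_infl)),
            cancer_set = sprintf("C%03d", seq_len(n_canc)))
}

# regnet from a bare edge list; roles from a gene_sets object
make_net <- function(edges, gs, id = "net", phenotype = "UC", mi = 1) {
  if (is.null(edges$mi)) edges$mi <- mi
  regulatory_network(edges, gs = gs, network_id = id, phenotype = phenotype)
}

# a random TF->target edge set: each target regulated by one TF
random_edges <- function(n_tfs, n_targets, seed) {
  set.seed(seed)
  data.frame(tf = sample(sprintf("TF%03d", seq_len(n_tfs)), n_targets,
                         replace = TRUE),
             gene = sprintf("G%04d", seq_len(n_targets)),
             mi = stats::runif(n_targets, 0.1, 1),
             stringsAsFactors = FALSE)
}

# collection of networks in phenotype groups: networks within a group share
# a group-specific base edge set with a fraction of targets rewired per
# network; optionally an extra "bridge" group of two networks labelled with
# different phenotypes
network_collection <- function(seed, per_group = 4, n_tfs = 15,
                               n_targets = 60, rewire = 0.1,
                               groups = c("UC", "CRC", "normal"),
                               bridge = FALSE) {
  set.seed(seed)
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  targets <- sprintf("G%04d", seq_len(n_targets))
  gs <- gene_sets(tfs, targets[seq_len(n_targets / 2)],
                  targets[-seq_len(n_targets / 2)])
  mk_group <- function(gname, members) {
    base <- sample(tfs, n_targets, replace = TRUE)
    lapply(seq_along(members), function(i) {
      tf <- base
      flip <- which(stats::runif(n_targets) < rewire)
      tf[flip] <- sample(tfs, length(flip), replace = TRUE)
      make_net(data.frame(tf = tf, gene = targets, mi = 1,
                          stringsAsFactors = FALSE),
               gs, id = paste0(gname, "_", i), phenotype = members[i])
    })
  }
  nets <- unlist(lapply(groups, function(g) mk_group(g, rep(g, per_group))),
                 recursive = FALSE)
  membership <- rep(groups, each = per_group)
  if (bridge) {
    bn <- mk_group("bridge", c("UC", "CRC"))
    bn[[1]]$network_id <- "bridge_UC"
    bn[[2]]$network_id <- "bridge_Ca"
    nets <- c(nets, bn)
    membership <- c(membership, "bridge", "bridge")
  }
  list(nets = nets, gs = gs, membership = membership)
}

# bivariate Gaussian sample with given correlation
rho_pair <- function(n, rho) {
  x <- stats::rnorm(n)
  list(x = x, y = rho * x + sqrt(1 - rho^2) * stats::rnorm(n))
}
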