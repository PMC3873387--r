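test_that("MI estimator: symmetry, monotone invariance, degenerate input", {
  set.seed(1)
  p <- rho_pair(200, 0.6)
  expect_equal(estimate_mi(p$x, p$y), estimate_mi(p$y, p$x))
  # rank-based: exactly invariant under strictly monotone transforms
  expect_identical(estimate_mi(p$x, p$y), estimate_mi(exp(p$x), p$y^3 + p$y))
  expect_warning(z <- estimate_mi(rep(1, 50), rnorm(50)), "degenerate")
  expect_identical(z, 0)
  expect_error(estimate_mi(1:10, 1:9), "same length")
})

test_that("MI is near zero for independent data and near the closed form
           for correlated Gaussians", {
  set.seed(42)
  expect_lt(estimate_mi(rnorm(500), rnorm(500)), 0.05)
  p <- rho_pair(5000, 0.8)
  expect_equal(estimate_mi(p$x, p$y), -0.5 * log(1 - 0.8^2),
               tolerance = 0.05 / 0.51)
})

test_that("self-MI dominates every cross pair from the same sample", {
  set.seed(3)
  X <- matrix(rnorm(20 * 100), 20, 100)
  self <- estimate_mi(X[1, ], X[1, ])
  cross <- vapply(2:20, function(i) estimate_mi(X[1, ], X[i, ]), numeric(1))
  expect_true(all(self > cross))
})

test_that("threshold calibration is monotone in the p-value and guarded", {
  m <- generate_model(5, 45, n_conditions = 2, seed = 2)
  ds <- simulate_dataset(m, "inflammation", 40, "D", seed = 5)
  th <- vapply(c(0.5, 0.05, 0.005), function(p)
    calibrate_mi_threshold(ds, pvalue = p, n_null = 2000, seed = 9),
    numeric(1))
  expect_true(all(diff(th) >= 0))
  # deterministic under the seed
  expect_identical(calibrate_mi_threshold(ds, 0.01, n_null = 1000, seed = 4),
                   calibrate_mi_threshold(ds, 0.01, n_null = 1000, seed = 4))
  expect_error(calibrate_mi_threshold(ds, pvalue = 0.001, n_null = 1000),
               "n_null")
})

test_that("DPI removes the weakest edge of each triangle, mark-then-delete", {
  tri <- data.frame(tf = c("TF001", "TF002", "TF001"),
                    gene = c("A", "A", "TF002"),
                    mi = c(0.5, 0.4, 0.3))
  out <- dpi_prune(tri, tolerance = 0)
  expect_equal(nrow(out), 2)
  expect_false(any(out$tf == "TF001" & out$gene == "TF002"))

  # tolerance 1 removes nothing; no triangles -> unchanged
  expect_equal(nrow(dpi_prune(tri, tolerance = 1)), 3)
  chain <- data.frame(tf = c("TF001", "TF002"), gene = c("A", "B"),
                      mi = c(0.9, 0.8))
  expect_identical(dpi_prune(chain), chain)

  # exact three-way tie: the lexicographically smallest endpoint pair goes
  tie <- data.frame(tf = c("TF001", "TF001", "TF002"),
                    gene = c("A", "TF002", "A"),
                    mi = c(0.5, 0.5, 0.5))
  out_tie <- dpi_prune(tie)
  expect_equal(nrow(out_tie), 2)
  expect_false(any(out_tie$tf == "TF001" & out_tie$gene == "A"))
})

test_that("DPI is idempotent on random weighted graphs", {
  for (s in 1:5) {
    e <- random_edges(6, 30, seed = s)
    # add TF-TF edges to create triangles
    e <- rbind(e, data.frame(tf = "TF001", gene = c("TF002", "TF003"),
                             mi = c(0.6, 0.55)))
    once <- dpi_prune(e)
    expect_identical(dpi_prune(once), once)
  }
})

test_that("DPI deletes the indirect edge of a linear chain", {
  set.seed(11)
  x <- rnorm(500)
  y <- 0.9 * x + 0.3 * rnorm(500)
  z <- 0.9 * y + 0.3 * rnorm(500)
  e <- data.frame(tf = c("TF001", "TF002", "TF001"),
                  gene = c("TF002", "G1", "G1"),
                  mi = c(estimate_mi(x, y), estimate_mi(y, z),
                         estimate_mi(x, z)))
  out <- dpi_prune(e)
  expect_setequal(paste(out$tf, out$gene),
                  c("TF001 TF002", "TF002 G1"))
})

test_that("network inference recovers a planted model and is deterministic", {
  m <- generate_model(10, 80, n_conditions = 2, frac_shared_edges = 0.8,
                      frac_dysregulated = 0.1, seed = 21)
  ds <- simulate_dataset(m, "inflammation", 100, "I1", seed = 22)
  net <- infer_network(ds, m$gene_sets, n_null = 2e4, seed = 1)
  planted <- m$edges_by_condition$inflammation
  pk <- paste(pmin(planted$tf, planted$gene), pmax(planted$tf, planted$gene))
  ik <- paste(pmin(net$edges$tf, net$edges$gene),
              pmax(net$edges$tf, net$edges$gene))
  expect_gt(mean(pk %in% ik), 0.9)   # recall
  expect_gt(mean(ik %in% pk), 0.9)   # precision

  net2 <- infer_network(ds, m$gene_sets, n_null = 2e4, seed = 1)
  expect_identical(net$edges, net2$edges)
})

test_that("inference is invariant to gene-row order and guards its inputs", {
  m <- generate_model(6, 40, n_conditions = 2, seed = 31)
  ds <- simulate_dataset(m, "cancer", 60, "C1", seed = 32)
  perm <- sample(length(ds$genes))
  ds_perm <- expression_dataset(ds$values[perm, ], "C1", "cancer")
  n1 <- infer_network(ds, m$gene_sets, n_null = 5e3, pvalue = 0.01, seed = 2)
  n2 <- infer_network(ds_perm, m$gene_sets, n_null = 5e3, pvalue = 0.01,
                      seed = 2)
  expect_identical(n1$edges, n2$edges)

  small <- expression_dataset(ds$values[, 1:10], "C1", "cancer")
  expect_error(infer_network(small, m$gene_sets), "at least 20")
  no_tf <- expression_dataset(ds$values[!ds$genes %in% m$tf_ids, ],
                              "C1", "cancer")
  expect_error(infer_network(no_tf, m$gene_sets), "no TFs")
})

test_that("hub-weighted planted models yield right-skewed TF degrees", {
  w <- (1:15)^-1.5
  m <- generate_model(15, 120, n_conditions = 2, seed = 51,
                      tf_weights = w / sum(w))
  ds <- simulate_dataset(m, "inflammation", 60, "H1", seed = 52)
  net <- infer_network(ds, m$gene_sets, n_null = 1e4, seed = 5)
  deg <- table(factor(net$edges$tf, levels = m$tf_ids)) +
    table(factor(net$edges$gene, levels = m$tf_ids))
  deg <- as.numeric(deg)
  expect_gt(mean(deg), stats::median(deg))  # heavy right tail: a few hubs
  expect_gt(max(deg), 3 * stats::median(deg))
})

test_that("pure-noise data with a stringent cutoff yields no edges", {
  set.seed(77)
  v <- matrix(rnorm(40 * 60, 8, 2), 40, 60,
              dimnames = list(c(sprintf("TF%03d", 1:5),
                                sprintf("G%04d", 1:35)),
                              sprintf("S%02d", 1:60)))
  ds <- expression_dataset(v, "noise", "UC")
  gs <- gene_sets(sprintf("TF%03d", 1:5), sprintf("G%04d", 1:17),
                  sprintf("G%04d", 18:35))
  net <- infer_network(ds, gs, pvalue = 5e-4, n_null = 1e4, seed = 3)
  expect_equal(nrow(net$edges), 0)
})

test_that("IC component extraction keeps TFs, IC genes, and the largest
           component", {
  gs <- tiny_gs()
  edges <- data.frame(
    tf = c("TF001", "TF001", "TF001", "TF001", "TF002", "TF002"),
    gene = c("I001", "I002", "C001", "X999", "I003", "C002"),
    mi = 1)
  nodes <- data.frame(gene = c("TF001", "TF002", "I001", "I002", "I003",
                               "C001", "C002", "X999"),
                      is_tf = c(TRUE, TRUE, rep(FALSE, 6)),
                      is_inflammation = c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                          FALSE, FALSE, FALSE),
                      is_cancer = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                                    TRUE, TRUE, FALSE))
  net <- regulatory_network(edges, nodes = nodes, network_id = "N")
  ic <- extract_ic_component(net, gs)
  # non-IC leaf dropped; 4-node component beats the 3-node one
  expect_setequal(ic$nodes$gene, c("TF001", "I001", "I002", "C001"))
  expect_equal(unname(ic$provenance$component_counts),
               c(1L, 2L, 1L))

  only_other <- regulatory_network(
    data.frame(tf = "TF001", gene = "X999", mi = 1),
    nodes = nodes[nodes$gene %in% c("TF001", "X999"), ], network_id = "N2")
  expect_error(extract_ic_component(only_other, gs), "empty")
})

test_that("network statistics match closed forms on small graphs", {
  gs <- tiny_gs()
  path <- make_net(data.frame(tf = c("TF001", "TF002"),
                              gene = c("I001", "I001"), mi = 1), gs)
  st <- network_stats(path)
  expect_equal(st$diameter, 2)
  expect_equal(st$density, 2 / 3)

  star <- make_net(data.frame(tf = "TF001",
                              gene = c("I001", "I002", "C001", "C002"),
                              mi = 1), gs)
  sts <- network_stats(star)
  expect_equal(sts$mean_betweenness_tf, 6)  # C(4,2) shortest paths via hub

  clique <- make_net(data.frame(
    tf = c("TF001", "TF001", "TF001", "TF002", "TF002", "TF003"),
    gene = c("TF002", "TF003", "TF004", "TF003", "TF004", "TF004"),
    mi = 1), gs, id = "K4")
  g <- network_stats(clique)
  expect_equal(g$density, 1)
  expect_equal(g$diameter, 1)

  two <- make_net(data.frame(tf = c("TF001", "TF002"),
                             gene = c("I001", "I002"), mi = 1), gs)
  expect_error(network_stats(two), "disconnected")
})
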