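test_that("candidate relationships are the union of common-TF neighborhoods", {
  gs <- tiny_gs()
  ni <- make_net(data.frame(tf = c("TF001", "TF001", "TF002"),
                            gene = c("I001", "I002", "C001")), gs, "NI")
  nc <- make_net(data.frame(tf = c("TF001", "TF001", "TF003"),
                            gene = c("I002", "C002", "C001")), gs, "NC")
  pairs <- candidate_relationships(ni, nc)
  # TF002 / TF003 are not common; TF001 contributes its union
  expect_setequal(paste(pairs$tf, pairs$gene),
                  c("TF001 I001", "TF001 I002", "TF001 C002"))

  # brute-force check on a 2-TF example with a TF-TF edge
  n1 <- make_net(data.frame(tf = c("TF001", "TF002", "TF001"),
                            gene = c("I001", "I002", "TF002")), gs, "A")
  n2 <- make_net(data.frame(tf = c("TF001", "TF002"),
                            gene = c("C001", "TF001")), gs, "B")
  got <- candidate_relationships(n1, n2)
  expect_setequal(paste(got$tf, got$gene),
                  c("TF001 I001", "TF001 C001", "TF001 TF002",
                    "TF002 I002"))
  # the TF-TF pair appears exactly once, anchored at the smaller id
  expect_equal(sum(got$gene == "TF002" | got$tf == "TF002" &
                     got$gene == "TF001"), 1)

  solo <- make_net(data.frame(tf = "TF005", gene = "I001"), gs, "S")
  expect_error(candidate_relationships(ni, solo), "no common TFs")
})

test_that("delta MI is zero on identical data and antisymmetric under swap", {
  m <- generate_model(5, 30, n_conditions = 2, seed = 3)
  di <- simulate_dataset(m, "inflammation", 40, "I1", seed = 4)
  dc <- simulate_dataset(m, "cancer", 40, "C1", seed = 5)
  pairs <- data.frame(tf = c("TF001", "TF002"), gene = c("G0001", "G0002"))
  same <- delta_mi(pairs, di, di)
  expect_true(all(same$delta_mi == 0))
  ab <- delta_mi(pairs, di, dc)
  ba <- delta_mi(pairs, dc, di)
  expect_equal(ab$delta_mi, -ba$delta_mi)
  expect_equal(ab$mi_inflammation, ba$mi_cancer)

  # pairs with genes absent from one dataset are dropped with a message
  pairs2 <- rbind(pairs, data.frame(tf = "TF001", gene = "MISSING"))
  expect_message(out <- delta_mi(pairs2, di, dc), "dropped")
  expect_equal(nrow(out), 2)
})

test_that("permutation null bookkeeping: size, determinism, symmetry", {
  m <- generate_model(5, 30, n_conditions = 2, seed = 6)
  di <- simulate_dataset(m, "inflammation", 30, "I1", seed = 7)
  dc <- simulate_dataset(m, "cancer", 30, "C1", seed = 8)
  pairs <- data.frame(tf = rep(sprintf("TF%03d", 1:5), each = 2),
                      gene = sprintf("G%04d", 1:10))
  null1 <- permutation_null(pairs, di, dc, n_perm = 1, seed = 1)
  expect_length(null1, 10)
  null2 <- permutation_null(pairs, di, dc, n_perm = 20, seed = 2)
  expect_identical(null2, permutation_null(pairs, di, dc, n_perm = 20,
                                           seed = 2))
  # symmetric around zero: mean within 2 standard errors
  expect_lt(abs(mean(null2)), 2 * sd(null2) / sqrt(length(null2)) + 0.02)

  pg <- permutation_null(pairs, di, dc, n_perm = 5, seed = 3,
                         method = "per-gene")
  expect_length(pg, 50)
})

test_that("empirical p-values and BH q-values follow the add-one step-up", {
  null <- 1:999 / 1000
  deltas <- data.frame(tf = c("a", "b", "c"), gene = c("x", "y", "z"),
                       mi_inflammation = 0, mi_cancer = 0,
                       delta_mi = c(2, -0.9985, 0.5005))
  sig <- test_dysregulation(deltas, null, fdr_cutoff = 0.05)
  all_tested <- attr(sig, "all")
  expect_equal(all_tested$p_empirical, c(0.001, 0.002, 0.5))
  expect_equal(all_tested$q_fdr, c(0.003, 0.003, 0.5))
  expect_equal(nrow(sig), 2)
  expect_equal(sig$direction, c("gain", "loss"))

  # observed delta beyond every null draw with 9999 draws: p = 1e-4
  one <- test_dysregulation(
    data.frame(tf = "a", gene = "x", mi_inflammation = 0, mi_cancer = 1,
               delta_mi = 5),
    null = rnorm(9999), fdr_cutoff = 0.05)
  expect_equal(attr(one, "all")$p_empirical, 1e-4)
})

test_that("intersection keeps simultaneous relationships and the largest
           component", {
  gs <- tiny_gs()
  mk <- function(tf, gene) data.frame(
    tf = tf, gene = gene, mi_inflammation = 0.5, mi_cancer = 0.1,
    delta_mi = -0.4, p_empirical = 1e-3, q_fdr = 1e-2, direction = "loss",
    stringsAsFactors = FALSE)
  l1 <- mk(c("TF001", "TF001"), c("I001", "I002"))
  l2 <- mk(c("TF001", "TF001"), c("I002", "C001"))
  dn <- intersect_and_build(list(l1, l2), gs)
  expect_equal(paste(dn$edges$tf, dn$edges$gene), "TF001 I002")

  # order-invariance and single-list identity
  dn2 <- intersect_and_build(list(l2, l1), gs)
  expect_equal(dn$edges[c("tf", "gene")], dn2$edges[c("tf", "gene")])
  single <- intersect_and_build(list(l1), gs)
  expect_equal(nrow(single$edges), 2)

  expect_error(intersect_and_build(list(l1, mk("TF002", "C002")), gs),
               "empty intersection")

  # largest connected component wins
  l3 <- mk(c("TF001", "TF001", "TF002"), c("I001", "I002", "C001"))
  dn3 <- intersect_and_build(list(l3), gs)
  expect_setequal(dn3$nodes$gene, c("TF001", "I001", "I002"))
  expect_equal(dn3$component_stats$n_tfs, 1)
})

test_that("node-role bookkeeping counts both conventions consistently", {
  gs <- gene_sets("TF001", c("I001", "B001"), c("C001", "B001"))
  mk <- function(gene) data.frame(
    tf = "TF001", gene = gene, mi_inflammation = 0.6, mi_cancer = 0.1,
    delta_mi = -0.5, p_empirical = 1e-3, q_fdr = 1e-2, direction = "loss",
    stringsAsFactors = FALSE)
  dn <- intersect_and_build(list(mk(c("I001", "C001", "B001"))), gs)
  s <- dn$component_stats
  expect_equal(s$n_nodes, 4)
  expect_equal(s$n_inflammation, 2)  # I001 and dual-annotated B001
  expect_equal(s$n_cancer, 2)
  expect_equal(s$n_inflammation_only + s$n_cancer_only + s$n_dual_ic +
                 s$n_tfs, s$n_nodes)
})

test_that("topology statistics match closed forms", {
  gs <- tiny_gs()
  mk <- function(tf, gene) data.frame(
    tf = tf, gene = gene, mi_inflammation = 0.5, mi_cancer = 0.1,
    delta_mi = -0.4, p_empirical = 1e-3, q_fdr = 1e-2, direction = "loss",
    stringsAsFactors = FALSE)
  # 5-node path TF001-I001-TF002-I002-TF003: mean pairwise distance 2
  path <- intersect_and_build(
    list(mk(c("TF001", "TF002", "TF002", "TF003"),
            c("I001", "I001", "I002", "I002"))), gs)
  topo <- dysregulated_topology(path)
  expect_equal(topo$average_shortest_path, 2)

  star <- intersect_and_build(
    list(mk(rep("TF001", 5), c("I001", "I002", "I003", "C001", "C002"))),
    gs)
  h <- dysregulated_topology(star)$degree_histogram
  expect_equal(as.vector(h[c("1", "5")]), c(5, 1))
  expect_true(is.na(dysregulated_topology(star)$gamma))  # 2 distinct degrees

  # exact power law p(k) = c * k^-2, k = 1..10: gamma 2, R^2 1
  k <- 1:10
  fit <- icnet:::.powerlaw_fit(k, k^-2 / sum(k^-2))
  expect_equal(fit$gamma, 2)
  expect_equal(fit$r_squared, 1)
})
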