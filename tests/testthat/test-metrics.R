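test_that("transitivity matches known graphs and brute-force counting", {
  expect_equal(net_transitivity(igraph::make_full_graph(3)), 1)
  expect_equal(net_transitivity(igraph::graph_from_literal(a - b - c)), 0)
  k4_minus <- igraph::delete_edges(igraph::make_full_graph(4), 1)
  expect_equal(net_transitivity(k4_minus), 0.75)
  expect_equal(net_transitivity(igraph::make_empty_graph(3,
                                                         directed = FALSE)), 0)
  set.seed(6)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.1, 0.7))
    expect_equal(net_transitivity(g), brute_transitivity(g))
  }
})

test_that("fast-greedy modules recover planted structure with correct Q", {
  one <- greedy_modules(igraph::make_full_graph(4))
  expect_identical(length(unique(one$membership)), 1L)
  expect_equal(one$modularity, 0)

  two_k3 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                   igraph::make_full_graph(3))
  part <- greedy_modules(two_k3)
  expect_identical(length(unique(part$membership)), 2L)
  expect_equal(part$modularity, 0.5)

  # ring of 4 cliques bridged by single edges: modules match the cliques
  ring <- igraph::disjoint_union(lapply(1:4, function(i)
    igraph::make_full_graph(3)))
  ring <- igraph::add_edges(ring, c(1, 4, 5, 7, 8, 10, 11, 2))
  part4 <- greedy_modules(ring)
  expect_identical(length(unique(part4$membership)), 4L)
  cliques <- rep(1:4, each = 3)
  expect_true(all(table(part4$membership, cliques) %in% c(0L, 3L)))
  # exhaustive check: no partition of the 12 nodes beats the clique split
  expect_equal(part4$modularity, brute_modularity(ring, cliques))
})

test_that("returned Q matches Newman's formula recomputed from the partition", {
  set.seed(7)
  for (i in 1:10) {
    g <- igraph::sample_gnp(sample(5:20, 1), 0.3)
    p <- greedy_modules(g)
    expect_equal(p$modularity,
                 brute_modularity(g, p$membership),
                 tolerance = 1e-12)
    expect_gte(p$modularity, 0) # never worse than the one-module split
  }
})

test_that("isolated nodes become singleton modules", {
  g <- igraph::add_edges(igraph::make_empty_graph(5, directed = FALSE),
                         c(1, 2, 2, 3))
  p <- greedy_modules(g)
  expect_identical(length(p$membership), 5L)
  tail_mods <- p$membership[4:5]
  expect_identical(length(unique(tail_mods)), 2L)
  empty <- greedy_modules(igraph::make_empty_graph(4, directed = FALSE))
  expect_identical(unname(empty$membership), 1:4)
  expect_equal(empty$modularity, 0)
})

test_that("within:between link ratio handles all denominator cases", {
  two_k3 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                   igraph::make_full_graph(3))
  bridged <- igraph::add_edges(two_k3, c(1, 4))
  part <- structure(list(membership = stats::setNames(rep(1:2, each = 3),
                                                      as.character(1:6)),
                         modularity = NA), class = "module_partition")
  expect_equal(within_between_ratio(bridged, part), 6)
  expect_identical(within_between_ratio(two_k3, part), Inf)
  # crossing-only graph under a bipartite-respecting partition
  star <- igraph::make_star(4, mode = "undirected")
  bip <- structure(list(membership = stats::setNames(c(1, 2, 2, 2),
                                                     as.character(1:4)),
                        modularity = NA), class = "module_partition")
  expect_equal(within_between_ratio(star, bip), 0)
  expect_true(is.nan(within_between_ratio(
    igraph::make_empty_graph(3, directed = FALSE))))
})

test_that("targeted-attack robustness matches closed forms", {
  for (n in 2:20)
    expect_equal(robustness_auc(igraph::make_full_graph(n))$auc, 0.5)
  single <- robustness_auc(igraph::make_empty_graph(1, directed = FALSE))
  expect_equal(single$auc, 0.5)
  expect_equal(single$curve$lcc_fraction, c(1, 0))
  # hub removal collapses the star: strictly less robust than K10
  star <- robustness_auc(igraph::make_star(10, mode = "undirected"))
  expect_lt(star$auc, 0.5)
  expect_equal(star$curve$lcc_fraction[2], 0.1)
})

test_that("robustness curve is well-formed and AUC label-invariant", {
  set.seed(8)
  for (i in 1:5) {
    g <- igraph::sample_gnp(12, 0.3)
    r <- robustness_auc(g)
    curve <- r$curve
    expect_equal(curve$fraction_removed, seq(0, 1, by = 1 / 12))
    lcc0 <- max(igraph::components(g)$csize) / 12
    expect_equal(curve$lcc_fraction[1], lcc0)
    expect_equal(curve$lcc_fraction[13], 0)
    expect_true(all(curve$lcc_fraction >= 0 & curve$lcc_fraction <= 1))
  }
  # label invariance on graphs whose attack sequence is orbit-symmetric
  for (g in list(igraph::make_full_graph(8),
                 igraph::make_star(7, mode = "undirected"))) {
    perm <- sample(igraph::vcount(g))
    gp <- igraph::permute(g, perm)
    expect_equal(robustness_auc(g)$auc, robustness_auc(gp)$auc)
  }
})

test_that("betweenness attack and no-recompute variants run and differ sanely", {
  g <- igraph::make_star(8, mode = "undirected")
  rb <- robustness_auc(g, attack = "betweenness")
  rd <- robustness_auc(g, attack = "degree", recompute = FALSE)
  expect_equal(rb$auc, robustness_auc(g)$auc) # hub first either way
  expect_equal(rd$curve$lcc_fraction[2], 1 / 8)
})

test_that("module composition tallies families per module", {
  two_k3 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                   igraph::make_full_graph(3))
  igraph::V(two_k3)$name <- paste0("t", 1:6)
  tax <- data.frame(taxon_id = paste0("t", 1:6),
                    family = c("A", "A", "B", "C", "C", "C"))
  mc <- module_composition(two_k3, taxonomy = tax)
  expect_identical(sum(mc$n_asv), 6L)
  expect_identical(mc$n_asv[mc$family == "C"], 3L)
  # empty network: singleton modules of family count 1
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- paste0("t", 1:3)
  mc2 <- module_composition(lone, taxonomy = tax)
  expect_true(all(mc2$n_asv == 1L))
  expect_identical(nrow(mc2), 3L)
})

test_that("the combined metrics report is internally consistent", {
  sim <- tiny_experiment(seed = 9)
  res <- infer_network(sim$counts, sim$design, timepoint = "peak",
                       kingdom = "prokaryote", seed = 9, n_subsamples = 10)
  rep <- network_metrics(res$network)
  expect_gte(rep$transitivity, 0)
  expect_lte(rep$transitivity, 1)
  expect_gte(rep$modularity, -0.5)
  expect_lte(rep$modularity, 1)
  n <- rep$n_nodes
  expect_lte(rep$robustness, 0.5 + 1 / (2 * n))
  expect_identical(rep$attack, "degree")
  expect_true(rep$recompute)
})
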