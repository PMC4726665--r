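path_net <- function(scores) {
  g <- igraph::make_graph(~ A - B - C)
  scored_network(g, scores)
}

test_that("an all-positive connected graph is returned whole", {
  net <- path_net(c(A = 1, B = 2, C = 0.5))
  for (m in c("exact", "heuristic")) {
    mod <- max_scoring_subnetwork(net, method = m)
    expect_setequal(mod$nodes, c("A", "B", "C"))
    expect_equal(mod$total_score, 3.5)
  }
})

test_that("bridging a mildly negative node pays; a deeply negative one does not", {
  pay <- path_net(c(A = 2, B = -1, C = 2))
  for (m in c("exact", "heuristic")) {
    mod <- max_scoring_subnetwork(pay, method = m)
    expect_setequal(mod$nodes, c("A", "B", "C"))
    expect_equal(mod$total_score, 3)
  }
  no_pay <- path_net(c(A = 2, B = -5, C = 2))
  for (m in c("exact", "heuristic")) {
    mod <- max_scoring_subnetwork(no_pay, method = m)
    expect_equal(length(mod$nodes), 1)
    expect_equal(mod$total_score, 2)
  }
})

test_that("the exact solver equals exhaustive enumeration on random graphs", {
  for (i in 1:12) {
    inst <- random_scored_graph(n = sample(6:12, 1), p = 0.3, seed = 100 + i)
    mod <- max_scoring_subnetwork(inst$net, method = "exact")
    oracle <- enum_best_connected(inst$adj, inst$scores)
    expect_equal(mod$total_score, oracle$score, tolerance = 1e-9)
    heur <- max_scoring_subnetwork(inst$net, method = "heuristic")
    expect_lte(heur$total_score, mod$total_score + 1e-9)
    # every returned module is connected
    for (m in list(mod, heur)) {
      if (length(m$nodes) > 1) {
        sub <- igraph::induced_subgraph(inst$net$graph, m$nodes)
        expect_true(igraph::is_connected(sub))
      }
    }
  }
})

test_that("all-negative scores yield the empty module only when allowed", {
  net <- path_net(c(A = -1, B = -2, C = -0.5))
  expect_length(max_scoring_subnetwork(net, allow_empty = TRUE)$nodes, 0)
  best <- max_scoring_subnetwork(net, allow_empty = FALSE)
  expect_equal(best$nodes, "C")
})

test_that("exact search above the size limit is refused with advice", {
  inst <- random_scored_graph(n = 15, p = 0.3, seed = 200)
  # force every node negative so the positive-merge reduction cannot shrink it
  sc <- -abs(inst$scores) - 0.1
  net <- scored_network(inst$net$graph, sc)
  expect_error(max_scoring_subnetwork(net, method = "exact",
                                      exact_limit = 5),
               "heuristic")
})

test_that("scored_network removes self-loops and keeps the largest component", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c"),
                                         c("c", "c"), c("d", "e")),
                                   directed = FALSE)
  net <- scored_network(g, c(a = 1, b = 1, c = 1, d = 5, e = 5))
  expect_setequal(igraph::V(net$graph)$name, c("a", "b", "c"))
  expect_false(any(igraph::which_loop(net$graph)))
  expect_error(max_scoring_subnetwork(
    structure(list(graph = g, scores = c(a = 1)), class = "scored_network")),
    "connected")
})

test_that("a single degenerate iteration collapses to the single-run module", {
  cfg <- sim_config(k_studies = 3, n_high = 15, n_low = 15, n_genes = 300,
                    network_nodes = 150, planted_module_size = 8,
                    deg_fraction = 0.04, smd_range = c(0.8, 0.8),
                    heterogeneity_tau2 = 0, seed = 41)
  sim <- simulate_dataset(cfg)
  cm <- consensus_module(sim$studies, sim$network, n_iter = 1,
                         resample = "none", phi = 0.4, n_perm = 60,
                         fdr = 0.001, seed = 42)
  # rebuild the single-run module through the same chain
  genes <- intersect(common_genes(sim$studies),
                     igraph::V(sim$network)$name)
  P <- vapply(seq_along(sim$studies), function(i) {
    ds <- sim$studies[[i]]
    sub <- study_dataset(ds$study_id, ds$matrix[genes, , drop = FALSE],
                         ds$groups, ds$platform_tag)
    sam_permutation_p(sub, n_perm = 60, seed = 42 + 17 + i)$p
  }, numeric(length(genes)))
  fisher_p <- pmax(pchisq(-2 * rowSums(log(P)), df = 2 * ncol(P),
                          lower.tail = FALSE), .Machine$double.xmin)
  names(fisher_p) <- genes
  sc <- node_scores(fisher_p, fit_bum(fisher_p), fdr = 0.001)
  single <- max_scoring_subnetwork(scored_network(sim$network, sc),
                                   method = "heuristic", allow_empty = TRUE)
  expect_setequal(cm$nodes, single$nodes)
  expect_true(all(cm$node_freq[cm$nodes] == 1))
})

test_that("consensus recovers a strongly planted module", {
  cfg <- sim_config(k_studies = 4, n_high = 30, n_low = 30, n_genes = 400,
                    network_nodes = 200, planted_module_size = 10,
                    deg_fraction = 0.025, smd_range = c(0.8, 0.8), seed = 43)
  sim <- simulate_dataset(cfg)
  cm <- consensus_module(sim$studies, sim$network, n_iter = 5,
                         n_perm = 80, fdr = 0.001, seed = 44)
  planted <- sim$truth$planted_module_nodes
  expect_gte(length(intersect(cm$nodes, planted)) / length(planted), 0.7)
  if (length(cm$nodes) > 1) {
    sub <- igraph::induced_subgraph(sim$network, cm$nodes)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("invalid consensus parameters are rejected", {
  cfg <- sim_config(k_studies = 2, n_high = 5, n_low = 5, n_genes = 150,
                    network_nodes = 120, deg_fraction = 0, seed = 45)
  sim <- simulate_dataset(cfg)
  expect_error(consensus_module(sim$studies, sim$network, phi = 1.2,
                                n_iter = 2),
               "phi")
  expect_error(consensus_module(sim$studies, sim$network, n_iter = 0),
               "n_iter")
})
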