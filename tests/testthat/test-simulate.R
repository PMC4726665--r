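test_that("generation is a pure function of the seed", {
  cfg <- sim_config(k_studies = 2, n_high = 5, n_low = 5, n_genes = 80,
                    network_nodes = 40, planted_module_size = 5, seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$studies[[1]]$matrix, b$studies[[1]]$matrix)
  expect_identical(a$studies[[2]]$matrix, b$studies[[2]]$matrix)
  expect_identical(igraph::as_edgelist(a$network),
                   igraph::as_edgelist(b$network))
  expect_identical(a$truth, b$truth)
})

test_that("no-signal configuration plants nothing", {
  cfg <- sim_config(k_studies = 2, n_high = 6, n_low = 6, n_genes = 100,
                    network_nodes = 50, deg_fraction = 0, seed = 3)
  sim <- simulate_studies(cfg)
  expect_length(sim$truth$deg_genes, 0)
  expect_length(sim$truth$planted_module_nodes, 0)
  # group-mean differences are pure sampling noise, centred at zero
  st <- metamodule:::group_stats(sim$studies[[1]]$matrix,
                                 sim$studies[[1]]$groups)
  diffs <- (st$mean_high - st$mean_low) / st$pooled_sd
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("large-sample per-gene SMD converges to the generating value", {
  cfg <- sim_config(k_studies = 1, n_high = 1000, n_low = 1000,
                    n_genes = 200, deg_fraction = 0.5,
                    smd_range = c(0.7, 0.7), heterogeneity_tau2 = 0,
                    network_nodes = 100, planted_module_size = 1, seed = 5)
  sim <- simulate_studies(cfg)
  st <- metamodule:::group_stats(sim$studies[[1]]$matrix,
                                 sim$studies[[1]]$groups)
  smd_hat <- (st$mean_high - st$mean_low) / st$pooled_sd
  deg <- sim$truth$deg_genes
  # per-gene sampling sd of the SMD is ~sqrt(2/n) ~ 0.045 here
  expect_lt(abs(mean(abs(smd_hat[deg])) - 0.7), 0.02)
  expect_true(all(abs(abs(smd_hat[deg]) - 0.7) < 0.2))
  expect_lt(abs(mean(smd_hat[setdiff(names(smd_hat), deg)])), 0.02)
})

test_that("per-study group sizes below 2 are rejected", {
  expect_error(sim_config(k_studies = 1, n_high = 1, n_low = 10),
               ">= 2")
})

test_that("network is simple, scale-free-grown, with the planted module connected", {
  cfg <- sim_config(k_studies = 2, n_high = 5, n_low = 5, n_genes = 600,
                    network_nodes = 500, network_attach = 2,
                    planted_module_size = 10, deg_fraction = 0.05, seed = 9)
  sim <- simulate_dataset(cfg)
  g <- sim$network
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
  expect_equal(igraph::vcount(g), 500)
  planted <- sim$truth$planted_module_nodes
  expect_length(planted, 10)
  expect_true(all(planted %in% sim$truth$deg_genes))
  expect_true(igraph::is_connected(igraph::induced_subgraph(g, planted)))
  expect_equal(nrow(sim$truth$planted_module_edges),
               igraph::ecount(igraph::induced_subgraph(g, planted)))
})

test_that("growth-phase edge count matches the closed form", {
  # without module wiring, n nodes at attachment a give n*a - a*(a+1)/2 edges
  cfg <- sim_config(k_studies = 2, n_high = 5, n_low = 5, n_genes = 500,
                    network_nodes = 500, network_attach = 2,
                    deg_fraction = 0, planted_module_size = 1, seed = 2)
  g <- simulate_network(cfg)
  expect_equal(igraph::ecount(g), 500 * 2 - 3)
  cfg3 <- sim_config(k_studies = 2, n_high = 5, n_low = 5, n_genes = 300,
                     network_nodes = 300, network_attach = 3,
                     deg_fraction = 0, planted_module_size = 1, seed = 2)
  expect_equal(igraph::ecount(simulate_network(cfg3)), 300 * 3 - 6)
})

test_that("single-node planted module is trivially connected", {
  cfg <- sim_config(k_studies = 2, n_high = 5, n_low = 5, n_genes = 100,
                    network_nodes = 60, planted_module_size = 1,
                    deg_fraction = 0.1, seed = 4)
  sim <- simulate_dataset(cfg)
  expect_length(sim$truth$planted_module_nodes, 1)
  expect_equal(nrow(sim$truth$planted_module_edges), 0)
})

test_that("two-platform emulation shrinks the common universe but keeps planted genes", {
  cfg <- sim_config(k_studies = 4, n_high = 6, n_low = 6, n_genes = 400,
                    network_nodes = 100, planted_module_size = 6,
                    deg_fraction = 0.05, two_platforms = TRUE, seed = 8)
  sim <- simulate_studies(cfg)
  universe <- common_genes(sim$studies)
  expect_lt(length(universe), 400)
  expect_true(all(sim$truth$planted_module_nodes %in% universe))
  expect_setequal(unique(vapply(sim$studies, `[[`, "", "platform_tag")),
                  c("P1", "P2"))
})
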