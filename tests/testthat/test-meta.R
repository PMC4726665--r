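test_that("Fisher combination handles the boundary and matches quadrature", {
  triv <- fisher_combine(rep(1, 6))
  expect_equal(triv$statistic, 0)
  expect_equal(triv$p, 1)
  expect_error(fisher_combine(c(0.5, 0)), "smooth")
  expect_error(fisher_combine(numeric(0)), "empty")

  res <- fisher_combine(rep(0.05, 6))
  expect_equal(res$statistic, 12 * log(20), tolerance = 1e-12)
  # quadrature oracle: integrate the chi-squared(12) density upper tail
  oracle <- integrate(function(x) dchisq(x, 12), res$statistic, Inf,
                      rel.tol = 1e-10)$value
  expect_equal(res$p, oracle, tolerance = 1e-8)
})

test_that("Fisher combined p is uniform under the uniform null", {
  set.seed(21)
  p_null <- replicate(2000, fisher_combine(runif(5))$p)
  ks <- ks.test(p_null, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Hedges' g and its variance follow the stated formulas", {
  res <- smd_per_study(20, 20, mean_high = 1, mean_low = 0, pooled_sd = 2)
  J <- 1 - 3 / (4 * 38 - 1)
  expect_equal(res$g, J * 0.5, tolerance = 1e-12)
  expect_equal(res$g, 0.4901, tolerance = 1e-4)
  expect_equal(res$var, J^2 * (40 / 400 + 0.25 / 76), tolerance = 1e-12)
  # antisymmetry and the equal-means case
  flip <- smd_per_study(20, 20, mean_high = 0, mean_low = 1, pooled_sd = 2)
  expect_equal(flip$g, -res$g)
  eq <- smd_per_study(10, 15, 2, 2, 1)
  expect_equal(eq$g, 0)
  expect_equal(eq$var, (25 / 150) * (1 - 3 / (4 * 23 - 1))^2)
  expect_error(smd_per_study(20, 20, 1, 0, 0), "positive")
})

test_that("Cochran's Q and I2 match the hand-computed case and the null law", {
  expect_equal(heterogeneity(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1)),
               list(Q = 0, I2 = 0))
  h <- heterogeneity(c(0.5, -0.5), c(0.1, 0.1))
  expect_equal(h$Q, 5)
  expect_equal(h$I2, 80)
  # homogeneous normal effects: Q ~ chi-squared with k-1 df
  set.seed(22)
  Qs <- replicate(2000, {
    heterogeneity(rnorm(5, 0, 1), rep(1, 5))$Q
  })
  q95 <- quantile(Qs, 0.95)
  expect_lt(abs(q95 - qchisq(0.95, 4)), 0.6)
  expect_error(heterogeneity(c(1, 2), c(0.1, -0.1)), "positive")
})

test_that("fixed-effect pooling matches the hand-computed case and the model gate", {
  res <- pool_effect(c(0.4, 0.6), c(0.04, 0.04))
  expect_equal(res$model, "fixed")
  expect_equal(res$pooled_smd, 0.5)
  expect_equal(res$pooled_se, sqrt(0.02), tolerance = 1e-12)
  expect_equal(res$z, 0.5 / sqrt(0.02), tolerance = 1e-12)
  # strong heterogeneity trips the gate
  het <- pool_effect(c(2, -2, 2), c(0.05, 0.05, 0.05))
  expect_equal(het$model, "random")
  expect_gt(het$tau2, 0)
  expect_gt(het$pooled_se, pool_effect(c(0.1, 0.12, 0.11),
                                       c(0.05, 0.05, 0.05))$pooled_se)
})

test_that("DerSimonian-Laird pooling agrees with metafor on random inputs", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    yi <- rnorm(k, 0.3, 0.4)
    vi <- runif(k, 0.02, 0.2)
    mine <- pool_effect(yi, vi)
    method <- if (mine$model == "random") "DL" else "FE"
    ref <- metafor::rma(yi = yi, vi = vi, method = method)
    expect_equal(mine$pooled_smd, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine$pooled_se, as.numeric(ref$se), tolerance = 1e-8)
    expect_equal(mine$Q, as.numeric(ref$QE), tolerance = 1e-8)
    # random-effects se is never smaller than fixed-effects se
    w <- 1 / vi
    expect_gte(mine$pooled_se + 1e-12, sqrt(1 / sum(w)))
  }
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("the fit recovers generating SMDs on homogeneous multi-study data", {
  cfg <- sim_config(k_studies = 6, n_high = 40, n_low = 40, n_genes = 500,
                    deg_fraction = 0.3, smd_range = c(0.3, 0.8),
                    heterogeneity_tau2 = 0, network_nodes = 100,
                    planted_module_size = 5, seed = 24)
  sim <- simulate_studies(cfg)
  fit <- meta_deg(sim$studies, n_perm = 30, seed = 25)
  est <- coef(fit)[sim$truth$deg_genes]
  bias <- mean(est - sim$truth$per_gene_true_smd)
  expect_lt(abs(bias), 0.05)
  # structure of the fit object
  expect_s3_class(fit, "metadeg")
  expect_named(coef(fit))
  expect_true(all(fit$table$I2 >= 0 & fit$table$I2 <= 100))
  expect_true(all((fit$table$model == "random") ==
                    (fit$table$Q_p < 0.05 | fit$table$I2 > 50)))
  s <- summary(fit)
  expect_s3_class(s, "summary.metadeg")
  expect_output(print(s), "meta-analysis")
})

test_that("forest data carries per-study rows plus the pooled row", {
  sim <- simulate_studies(sim_config(k_studies = 3, n_high = 10, n_low = 10,
                                     n_genes = 120, network_nodes = 50,
                                     deg_fraction = 0.1,
                                     planted_module_size = 3, seed = 26))
  fit <- meta_deg(sim$studies, n_perm = 20, seed = 27)
  g <- fit$table$gene[1]
  fd <- forest_data(fit, g)
  expect_equal(nrow(fd), 4)
  expect_equal(fd$study[4], "pooled")
  expect_true(all(fd$ci_lo <= fd$g & fd$g <= fd$ci_hi))
  expect_equal(fd$g[4], unname(coef(fit)[g]))
  expect_error(forest_data(fit, "nope"), "not in fit")
})

test_that("the permutation effect-size p-option is calibrated against the normal one", {
  sim <- simulate_studies(sim_config(k_studies = 3, n_high = 12, n_low = 12,
                                     n_genes = 150, network_nodes = 50,
                                     deg_fraction = 0, seed = 28))
  norm_fit <- meta_deg(sim$studies, n_perm = 20, seed = 29)
  perm_fit <- meta_deg(sim$studies, n_perm = 20, seed = 29,
                       es_p_method = "permutation")
  # same z's, and the two null p-values broadly agree on ranking
  expect_equal(norm_fit$table$z, perm_fit$table$z)
  expect_gt(cor(norm_fit$table$es_p, perm_fit$table$es_p,
                method = "spearman"), 0.95)
})
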