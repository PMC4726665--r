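#' Simulation configuration for multi-study expression data
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The defaults emulate a six-study two-group (high vs low phenotype)
#' microarray meta-analysis design with unequal per-group sample sizes in
#' the 9--45 range, a scale-free interaction network, and a connected
#' differential module planted among the differentially expressed genes.
#'
#' @param k_studies number of studies.
#' @param n_high,n_low integer vectors of per-study group sizes (recycled to
#'   length `k_studies`); every entry must be at least 2.
#' @param n_genes number of genes on the (full) platform.
#' @param deg_fraction fraction of genes that are truly differentially
#'   expressed, in `[0, 1]`.
#' @param smd_range length-2 numeric, the (low, high) magnitudes from which
#'   each DEG's standardized mean difference is drawn uniformly; the sign is
#'   random per gene.
#' @param heterogeneity_tau2 between-study variance of the per-study true
#'   SMD around the gene-level value (injected on the SMD scale).
#' @param network_nodes number of genes carried on the interaction network
#'   (the first `network_nodes` genes of the universe).
#' @param network_attach preferential-attachment edges added per new node.
#' @param planted_module_size number of nodes in the planted connected
#'   differential module (capped at the number of DEGs).
#' @param two_platforms if `TRUE`, half the studies are assigned a second
#'   platform tag and each platform half drops its own disjoint random 10%
#'   of genes, so the cross-study common universe is a strict subset.
#' @param seed integer seed making generation a pure function of the config.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(k_studies = 6L,
                       n_high = c(40L, 14L, 10L, 45L, 10L, 10L),
                       n_low  = c(40L, 12L,  9L, 39L, 10L, 10L),
                       n_genes = 2000L,
                       deg_fraction = 0.05,
                       smd_range = c(0.4, 0.8),
                       heterogeneity_tau2 = 0.02,
                       network_nodes = 500L,
                       network_attach = 2L,
                       planted_module_size = 12L,
                       two_platforms = FALSE,
                       seed = 1L) {
  stopifnot_scalar_count(k_studies, "k_studies")
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(network_nodes, "network_nodes")
  stopifnot_scalar_count(network_attach, "network_attach")
  stopifnot_scalar_count(planted_module_size, "planted_module_size", min = 0L)
  n_high <- rep_len(as.integer(n_high), k_studies)
  n_low <- rep_len(as.integer(n_low), k_studies)
  if (any(n_high < 2L) || any(n_low < 2L))
    stop("all per-study group sizes must be >= 2 (pooled SD is undefined below that)",
         call. = FALSE)
  if (!is.numeric(deg_fraction) || deg_fraction < 0 || deg_fraction > 1)
    stop("'deg_fraction' must be in [0, 1]", call. = FALSE)
  if (length(smd_range) != 2L || !all(is.finite(smd_range)) ||
      any(smd_range < 0) || smd_range[1] > smd_range[2])
    stop("'smd_range' must be finite non-negative (low, high) magnitudes",
         call. = FALSE)
  if (!is.finite(heterogeneity_tau2) || heterogeneity_tau2 < 0)
    stop("'heterogeneity_tau2' must be a finite non-negative variance",
         call. = FALSE)
  if (planted_module_size > network_nodes)
    stop("'planted_module_size' cannot exceed 'network_nodes'", call. = FALSE)
  if (network_nodes > n_genes)
    stop("'network_nodes' cannot exceed 'n_genes'", call. = FALSE)
  structure(list(k_studies = as.integer(k_studies), n_high = n_high,
                 n_low = n_low, n_genes = as.integer(n_genes),
                 deg_fraction = deg_fraction, smd_range = as.numeric(smd_range),
                 heterogeneity_tau2 = heterogeneity_tau2,
                 network_nodes = as.integer(network_nodes),
                 network_attach = as.integer(network_attach),
                 planted_module_size = as.integer(planted_module_size),
                 two_platforms = isTRUE(two_platforms),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' One study's expression matrix with two-group labels
#'
#' @param study_id study identifier.
#' @param matrix numeric gene x sample matrix of log2 expression with unique
#'   rownames (gene or probe IDs) and colnames (sample IDs).
#' @param groups character vector (length = samples) of `"high"` / `"low"`
#'   labels.
#' @param platform_tag free-text platform label.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(study_id, matrix, groups, platform_tag = "sim") {
  groups <- check_groups(groups)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix", call. = FALSE)
  if (length(groups) != ncol(matrix))
    stop("one group label per sample is required", call. = FALSE)
  if (anyDuplicated(rownames(matrix)))
    stop("row (gene) IDs must be unique", call. = FALSE)
  if (sum(groups == "high") < 2L || sum(groups == "low") < 2L)
    stop("each group must contain at least 2 samples", call. = FALSE)
  structure(list(study_id = as.character(study_id), matrix = matrix,
                 groups = groups, platform_tag = as.character(platform_tag)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset '%s': %d genes x %d samples (%d high / %d low), platform %s\n",
              x$study_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$groups == "high"), sum(x$groups == "low"), x$platform_tag))
  invisible(x)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate multi-study two-group expression data with planted DEGs
#'
#' Generates `k_studies` gene x sample log2 expression matrices. Baseline
#' expression per gene is normal around a gene-specific mean (mean ~
#' N(7, 1.5^2), within-group SD ~ Uniform(0.3, 1)). A fraction
#' `deg_fraction` of genes carries a true group difference: gene g's SMD is
#' drawn once from `smd_range` (random sign), then perturbed per study by
#' N(0, `heterogeneity_tau2`), and converted to a raw mean shift by
#' multiplying with the gene's SD. A connected module of
#' `planted_module_size` network genes is reserved among the DEGs; its
#' edges are wired by [simulate_network()].
#'
#' @param config a [sim_config()].
#' @return A list with `studies` (list of [study_dataset()]) and `truth`
#'   (list with `deg_genes`, `per_gene_true_smd`, `per_study_smd` matrix,
#'   `planted_module_nodes`, `planted_module_edges` — the latter filled in
#'   by [simulate_network()] / [simulate_dataset()]).
#' @export
simulate_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- gene_ids(config$n_genes)
    n_deg <- round(config$deg_fraction * config$n_genes)
    planted <- character(0)
    deg <- character(0)
    if (n_deg > 0L) {
      m <- min(config$planted_module_size, n_deg)
      planted <- sample(genes[seq_len(config$network_nodes)], m)
      extra <- sample(setdiff(genes, planted), n_deg - m)
      deg <- c(planted, extra)
    }
    smd <- setNames(numeric(config$n_genes), genes)
    smd[deg] <- runif(length(deg), config$smd_range[1], config$smd_range[2]) *
      sample(c(-1, 1), length(deg), replace = TRUE)

    base_mean <- rnorm(config$n_genes, 7, 1.5)
    base_sd <- runif(config$n_genes, 0.3, 1.0)

    # per-study true SMD = gene SMD + between-study perturbation
    per_study_smd <- matrix(0, config$n_genes, config$k_studies,
                            dimnames = list(genes, NULL))
    if (length(deg))
      per_study_smd[deg, ] <- smd[deg] +
        rnorm(length(deg) * config$k_studies,
              0, sqrt(config$heterogeneity_tau2))

    drop_sets <- list(character(0), character(0))
    plat <- rep("P1", config$k_studies)
    if (config$two_platforms && config$k_studies >= 2L) {
      plat[seq(ceiling(config$k_studies / 2) + 1L, config$k_studies)] <- "P2"
      n_drop <- round(0.1 * config$n_genes)
      droppable <- setdiff(genes, planted)
      d1 <- sample(droppable, min(n_drop, length(droppable) %/% 2))
      d2 <- sample(setdiff(droppable, d1), min(n_drop, length(droppable) %/% 2))
      drop_sets <- list(d1, d2)
    }

    studies <- vector("list", config$k_studies)
    for (i in seq_len(config$k_studies)) {
      n1 <- config$n_high[i]; n2 <- config$n_low[i]
      delta <- per_study_smd[, i] * base_sd
      mu_hi <- base_mean + delta / 2
      mu_lo <- base_mean - delta / 2
      x_hi <- matrix(rnorm(config$n_genes * n1, mu_hi, base_sd),
                     config$n_genes, n1)
      x_lo <- matrix(rnorm(config$n_genes * n2, mu_lo, base_sd),
                     config$n_genes, n2)
      mat <- cbind(x_hi, x_lo)
      rownames(mat) <- genes
      colnames(mat) <- sprintf("s%d_%03d", i, seq_len(n1 + n2))
      keep <- if (plat[i] == "P1") setdiff(genes, drop_sets[[1]])
              else setdiff(genes, drop_sets[[2]])
      studies[[i]] <- study_dataset(sprintf("study%d", i),
                                    mat[keep, , drop = FALSE],
                                    rep(c("high", "low"), c(n1, n2)),
                                    platform_tag = plat[i])
    }
    truth <- list(deg_genes = sort(deg),
                  per_gene_true_smd = smd[deg],
                  per_study_smd = per_study_smd[deg, , drop = FALSE],
                  planted_module_nodes = sort(planted),
                  planted_module_edges = NULL)
    list(studies = studies, truth = truth)
  })
}

#' Simulate a scale-free interaction network with a wired-in planted module
#'
#' Grows an undirected simple graph on the first `network_nodes` genes by
#' preferential attachment (each new node attaches to
#' `min(network_attach, existing)` distinct nodes with probability
#' proportional to degree + 1), then wires the planted module nodes into a
#' connected subgraph by adding a random path through them. No self-loops
#' or multi-edges are created; for `n` nodes and attachment `a` the growth
#' phase contributes exactly `n*a - a*(a+1)/2` edges (for `n > a`).
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_studies()] (used
#'   for the planted module nodes); may be `NULL` for a plain network.
#' @return An [igraph::graph] with vertex names equal to gene IDs.
#' @export
simulate_network <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$network_nodes
  a <- config$network_attach
  genes <- gene_ids(config$n_genes)[seq_len(n)]
  with_seed(config$seed + 1L, {
    deg <- integer(n)
    from <- integer(0); to <- integer(0)
    if (n >= 2L) for (v in 2:n) {
      k <- min(a, v - 1L)
      tgt <- sample.int(v - 1L, k, prob = deg[seq_len(v - 1L)] + 1)
      from <- c(from, rep.int(v, k)); to <- c(to, tgt)
      deg[v] <- deg[v] + k
      deg[tgt] <- deg[tgt] + 1L
    }
    g <- igraph::make_empty_graph(0, directed = FALSE) +
      igraph::vertices(genes)
    if (length(from))
      g <- igraph::add_edges(g, rbind(genes[from], genes[to]))
    planted <- if (is.null(truth)) character(0) else truth$planted_module_nodes
    if (length(planted) >= 2L) {
      ord <- sample(planted)
      new_edges <- cbind(ord[-length(ord)], ord[-1])
      g <- igraph::add_edges(g, t(new_edges))
      g <- igraph::simplify(g)
    }
    g
  })
}

#' Simulate a complete multi-study dataset with network and ground truth
#'
#' Convenience wrapper running [simulate_studies()] and
#' [simulate_network()] and recording the planted module's induced edges in
#' the ground truth.
#'
#' @inheritParams simulate_studies
#' @return A list with `studies`, `network` (igraph) and `truth`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_studies(config)
  net <- simulate_network(config, sim$truth)
  planted <- sim$truth$planted_module_nodes
  if (length(planted) >= 2L) {
    sub <- igraph::induced_subgraph(net, planted)
    el <- igraph::as_edgelist(sub)
    sim$truth$planted_module_edges <-
      data.frame(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]))
  } else {
    sim$truth$planted_module_edges <- data.frame(from = character(0),
                                                 to = character(0))
  }
  list(studies = sim$studies, network = net, truth = sim$truth)
}
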