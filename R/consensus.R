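#' Consensus module by resampling
#'
#' Runs the full per-iteration chain — resample samples within each study,
#' SAM permutation p-values, Fisher combination, beta-uniform mixture fit,
#' node scoring at the chosen FDR, maximum-scoring subnetwork — `n_iter`
#' times, accumulates how often every node and edge appears in the
#' iteration modules, scores the network by `frequency - phi`, and solves
#' for the maximum-scoring subnetwork on those consensus scores. The
#' result contains the maximally robust nodes and edges.
#'
#' Resampling is a stratified bootstrap by default (samples drawn with
#' replacement within each group, preserving group sizes), which preserves
#' the group signal while perturbing the sampling; `"permute"` shuffles
#' the group labels instead (a null-generating scheme, useful for
#' calibration); `"none"` reuses the original data in every iteration
#' (degenerate, for testing the single-iteration collapse).
#'
#' @param studies list of [study_dataset()] objects.
#' @param network [igraph::graph] or two-column edge-list data frame.
#' @param n_iter number of resampling iterations (the reference analysis
#'   design uses 100).
#' @param fdr BUM node-score FDR level (default 0.001).
#' @param resample `"bootstrap"`, `"permute"`, or `"none"`.
#' @param phi consensus score offset in (0, 1): a node must appear in more
#'   than `phi` of the iterations to score positive.
#' @param n_perm SAM permutations per study per iteration.
#' @param s0 SAM fudge constant (see [sam_scores()]).
#' @param method solver passed to [max_scoring_subnetwork()].
#' @param seed integer seed; the whole procedure is a pure function of it.
#' @return An object of class `consensus_module` (also a
#'   `network_module`): nodes, induced edges, total consensus score,
#'   `node_freq` / `edge_freq` over all iterations, `n_iter`, `n_failed`.
#' @export
consensus_module <- function(studies, network, n_iter = 100L, fdr = 0.001,
                             resample = c("bootstrap", "permute", "none"),
                             phi = 0.5, n_perm = 200L, s0 = "auto",
                             method = "heuristic", seed = 1L) {
  resample <- match.arg(resample)
  stopifnot_scalar_count(n_iter, "n_iter")
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 1)
    stop("'phi' must be in (0, 1)", call. = FALSE)
  if (is.data.frame(network))
    network <- igraph::graph_from_data_frame(network[, 1:2], directed = FALSE)
  network <- igraph::simplify(network)
  genes <- intersect(common_genes(studies), igraph::V(network)$name)
  if (length(genes) < 100L)
    stop("fewer than 100 genes shared by the studies and the network",
         call. = FALSE)

  node_count <- setNames(numeric(length(genes)), genes)
  edge_count <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(n_iter)) {
    mod_b <- tryCatch({
      studies_b <- with_seed(seed + 17L * b, {
        lapply(studies, resample_study, mode = resample)
      })
      P <- vapply(seq_along(studies_b), function(i) {
        ds <- studies_b[[i]]
        sub <- study_dataset(ds$study_id, ds$matrix[genes, , drop = FALSE],
                             ds$groups, ds$platform_tag)
        sam_permutation_p(sub, n_perm = n_perm, s0 = s0,
                          seed = seed + 17L * b + i)$p
      }, numeric(length(genes)))
      fisher_p <- pchisq(-2 * rowSums(log(P)), df = 2 * ncol(P),
                         lower.tail = FALSE)
      fisher_p <- pmax(fisher_p, .Machine$double.xmin)
      names(fisher_p) <- genes
      fit <- fit_bum(fisher_p)
      sc <- node_scores(fisher_p, fit, fdr = fdr)
      net_b <- scored_network(network, sc, fdr = fdr)
      max_scoring_subnetwork(net_b, method = method, allow_empty = TRUE)
    }, error = function(e) {
      warning(sprintf("iteration %d failed: %s", b, conditionMessage(e)))
      NULL
    })
    if (is.null(mod_b)) { n_failed <- n_failed + 1L; next }
    if (length(mod_b$nodes)) {
      node_count[mod_b$nodes] <- node_count[mod_b$nodes] + 1
      if (nrow(mod_b$edges)) {
        keys <- paste(mod_b$edges$from, mod_b$edges$to, sep = "|")
        hit <- keys %in% names(edge_count)
        edge_count[keys[hit]] <- edge_count[keys[hit]] + 1
        if (any(!hit))
          edge_count <- c(edge_count, setNames(rep(1, sum(!hit)),
                                               keys[!hit]))
      }
    }
  }
  if (n_failed > n_iter / 2)
    stop(sprintf("%d of %d consensus iterations failed", n_failed, n_iter),
         call. = FALSE)
  n_ok <- n_iter - n_failed
  node_freq <- node_count / n_ok
  edge_freq <- edge_count / n_ok

  consensus_scores <- node_freq - phi
  net_c <- scored_network(network, consensus_scores, fdr = fdr)
  final <- max_scoring_subnetwork(net_c, method = method, allow_empty = TRUE)
  out <- new_module(final$nodes, net_c$graph, net_c$scores, final$method,
                    node_freq = node_freq, edge_freq = edge_freq)
  out$n_iter <- as.integer(n_iter)
  out$n_failed <- n_failed
  out$phi <- phi
  class(out) <- c("consensus_module", class(out))
  out
}

#' @export
print.consensus_module <- function(x, ...) {
  cat(sprintf("consensus_module: %d nodes, %d edges over %d iterations (%d failed), phi = %.2f\n",
              length(x$nodes), nrow(x$edges), x$n_iter, x$n_failed, x$phi))
  if (length(x$nodes)) {
    cat(sprintf("  node frequencies in module: %.2f-%.2f; total consensus score %.3f\n",
                min(x$node_freq[x$nodes]), max(x$node_freq[x$nodes]),
                x$total_score))
  }
  invisible(x)
}

# Resample one study: stratified bootstrap, label permutation, or identity.
resample_study <- function(ds, mode) {
  if (mode == "none") return(ds)
  if (mode == "bootstrap") {
    idx_hi <- which(ds$groups == "high")
    idx_lo <- which(ds$groups == "low")
    take <- c(sample(idx_hi, length(idx_hi), replace = TRUE),
              sample(idx_lo, length(idx_lo), replace = TRUE))
    mat <- ds$matrix[, take, drop = FALSE]
    colnames(mat) <- sprintf("%s_b%03d", colnames(ds$matrix)[take],
                             seq_along(take))
    return(study_dataset(ds$study_id, mat, ds$groups[take], ds$platform_tag))
  }
  # permute: shuffle labels across all samples
  study_dataset(ds$study_id, ds$matrix, sample(ds$groups), ds$platform_tag)
}
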