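# Independent oracles and fixture builders used across the suite.

# Small two-group study with optional per-gene mean shifts (delta on the
# "high" group), built directly from rnorm.
make_toy_study <- function(n_genes = 50, n1 = 6, n2 = 6, delta = 0,
                           sd = 1, seed = 1, study_id = "toy") {
  set.seed(seed)
  delta <- rep_len(delta, n_genes)
  hi <- matrix(rnorm(n_genes * n1, 5 + delta, sd), n_genes, n1)
  lo <- matrix(rnorm(n_genes * n2, 5, sd), n_genes, n2)
  mat <- cbind(hi, lo)
  rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
  colnames(mat) <- sprintf("s%02d", seq_len(n1 + n2))
  study_dataset(study_id, mat, rep(c("high", "low"), c(n1, n2)))
}

# Textbook equal-variance two-sample t statistic, the oracle for SAM with
# s0 = 0.
t_oracle <- function(x_high, x_low) {
  n1 <- length(x_high); n2 <- length(x_low)
  sp2 <- ((n1 - 1) * var(x_high) + (n2 - 1) * var(x_low)) / (n1 + n2 - 2)
  (mean(x_high) - mean(x_low)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Brute-force maximum-score connected induced subgraph by enumerating all
# 2^n vertex subsets (adjacency matrix in, character node set out).
enum_best_connected <- function(adj_mat, scores) {
  n <- nrow(adj_mat)
  stopifnot(n <= 16)
  best_score <- -Inf; best_set <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) > 1) {
      # BFS connectivity on the induced subgraph
      seen <- S[1]; frontier <- S[1]
      while (length(frontier)) {
        nb <- which(colSums(adj_mat[frontier, , drop = FALSE]) > 0)
        frontier <- setdiff(intersect(nb, S), seen)
        seen <- union(seen, frontier)
      }
      if (length(seen) < length(S)) next
    }
    sc <- sum(scores[S])
    if (sc > best_score) { best_score <- sc; best_set <- S }
  }
  list(score = best_score, set = best_set)
}

# Random connected graph with mixed-sign scores as a scored_network.
random_scored_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  scores <- setNames(round(rnorm(n, 0, 2), 2), igraph::V(g)$name)
  list(net = scored_network(g, scores), adj = adj, scores = scores)
}

# Sample p-values from the beta-uniform mixture with density
# lambda + (1 - lambda) * a * p^(a - 1).
rbum <- function(n, lambda, a) {
  noise <- runif(n) < lambda
  p <- numeric(n)
  p[noise] <- runif(sum(noise))
  p[!noise] <- runif(sum(!noise))^(1 / a)
  p
}

bum_loglik <- function(p, lambda, a) {
  sum(log(lambda + (1 - lambda) * a * p^(a - 1)))
}
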