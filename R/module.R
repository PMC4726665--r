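#' Build a scored network from a graph and per-gene scores
#'
#' Restricts an interaction graph to the scored genes, removes self-loops
#' and multi-edges, and keeps the largest connected component — the
#' preprocessing module search operates on.
#'
#' @param graph an [igraph::graph] with gene IDs as vertex names, or a
#'   two-column edge-list data frame.
#' @param scores named numeric vector of node scores (e.g. from
#'   [node_scores()]).
#' @param fdr the FDR level the scores were derived at (bookkeeping).
#' @return An object of class `scored_network`: list with `graph` (igraph
#'   with `score` vertex attribute), `scores`, `fdr`.
#' @export
scored_network <- function(graph, scores, fdr = NA_real_) {
  if (is.data.frame(graph))
    graph <- igraph::graph_from_data_frame(graph[, 1:2], directed = FALSE)
  stopifnot(igraph::is_igraph(graph))
  if (is.null(names(scores)) || anyNA(names(scores)))
    stop("'scores' must be a fully named vector", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("all node scores must be finite", call. = FALSE)
  keep <- intersect(igraph::V(graph)$name, names(scores))
  if (length(keep) == 0L)
    stop("no graph vertex carries a score", call. = FALSE)
  g <- igraph::induced_subgraph(graph, keep)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  largest <- which.max(comp$csize)
  g <- igraph::induced_subgraph(g, igraph::V(g)$name[comp$membership == largest])
  igraph::V(g)$score <- unname(scores[igraph::V(g)$name])
  structure(list(graph = g, scores = scores[igraph::V(g)$name], fdr = fdr),
            class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("scored_network: %d nodes / %d edges (largest component), %d positive scores, fdr = %s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(x$scores > 0), format(x$fdr)))
  invisible(x)
}

new_module <- function(nodes, graph, scores, method,
                       node_freq = NULL, edge_freq = NULL) {
  nodes <- sort(nodes)
  if (length(nodes)) {
    sub <- igraph::induced_subgraph(graph, nodes)
    el <- igraph::as_edgelist(sub)
    edges <- data.frame(from = pmin(el[, 1], el[, 2]),
                        to = pmax(el[, 1], el[, 2]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0))
  }
  structure(list(nodes = nodes, edges = edges,
                 total_score = sum(scores[nodes]),
                 scores = scores[nodes], method = method,
                 node_freq = node_freq, edge_freq = edge_freq),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  cat(sprintf("network_module (%s): %d nodes, %d edges, total score %.3f\n",
              x$method, length(x$nodes), nrow(x$edges), x$total_score))
  if (!is.null(x$node_freq))
    cat(sprintf("  consensus node frequencies: %.2f-%.2f\n",
                if (length(x$nodes)) min(x$node_freq[x$nodes]) else NA,
                if (length(x$nodes)) max(x$node_freq[x$nodes]) else NA))
  invisible(x)
}

#' @export
plot.network_module <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = data.frame(name = x$nodes))
  cols <- ifelse(x$scores[x$nodes] > 0, "tomato", "lightsteelblue")
  igraph::plot.igraph(g, vertex.color = cols, vertex.size = 18,
                      vertex.label.cex = 0.7, ...)
  invisible(x)
}

# --- exact solver -----------------------------------------------------------

# Merge each connected component of positive-score nodes into one supernode
# (score = component sum). An optimal connected solution that touches a
# positive component always contains all of it, so the reduction is lossless.
reduce_positive <- function(g, scores) {
  pos <- names(scores)[scores > 0]
  mapping <- seq_len(igraph::vcount(g))
  if (length(pos) >= 2L) {
    sub <- igraph::induced_subgraph(g, pos)
    comp <- igraph::components(sub)
    idx <- match(igraph::V(sub)$name, igraph::V(g)$name)
    for (cid in seq_len(comp$no)) {
      members <- idx[comp$membership == cid]
      mapping[members] <- members[1]
    }
  }
  mapping <- match(mapping, unique(mapping))
  gc <- igraph::contract(g, mapping, vertex.attr.comb = list(
    name = function(v) paste(sort(v), collapse = "|"), score = "sum"))
  gc <- igraph::simplify(gc)
  gc
}

# Exhaustive-with-pruning search for the maximum-score connected induced
# subgraph. Enumerates every connected vertex subset once via the standard
# include/exclude expansion and prunes branches whose optimistic bound
# (current + all remaining positive scores) cannot beat the incumbent.
exact_best_connected <- function(adj, scores) {
  n <- length(scores)
  best_score <- -Inf
  best_set <- integer(0)
  pos_total <- sum(scores[scores > 0])

  grow <- function(S, S_score, ext, banned) {
    if (S_score > best_score) {
      best_score <<- S_score
      best_set <<- S
    }
    if (length(ext) == 0L) return()
    # optimistic bound: take every positive vertex not banned and not in S
    avail <- setdiff(which(scores > 0), c(S, banned))
    if (S_score + sum(scores[avail]) <= best_score) return()
    u <- ext[1]
    rest <- ext[-1]
    # include u
    new_ext <- union(rest, setdiff(adj[[u]], c(S, u, banned, rest)))
    grow(c(S, u), S_score + scores[u], new_ext, banned)
    # exclude u for this whole subtree
    grow(S, S_score, rest, c(banned, u))
  }

  # each connected subgraph is enumerated from its highest-priority vertex
  # only: later starts ban all earlier ones
  starts <- order(scores, decreasing = TRUE)
  for (i in seq_len(n)) {
    v <- starts[i]
    earlier <- starts[seq_len(i - 1L)]
    grow(v, scores[v], setdiff(adj[[v]], c(v, earlier)), earlier)
  }
  list(score = best_score, set = best_set)
}

#' Maximum-scoring connected subnetwork
#'
#' Finds the connected vertex subset with maximal summed node score on a
#' preprocessed [scored_network()]. The exact method merges adjacent
#' positive-score nodes into supernodes and then runs a branch-and-bound
#' enumeration of connected subsets, guaranteed optimal up to
#' `exact_limit` reduced nodes. The heuristic grows the best
#' positive-score component and greedily merges other positive components
#' whenever the connecting path's negative-score cost is smaller than the
#' component's gain, then prunes negative leaves.
#'
#' @param net a [scored_network()] (connected by construction).
#' @param method `"auto"` (exact when the reduced graph is small enough,
#'   else heuristic), `"exact"`, or `"heuristic"`.
#' @param allow_empty if `TRUE` and every score is negative, return the
#'   empty module (score 0) instead of the best single node.
#' @param exact_limit maximal reduced-graph size for the exact search.
#' @return A `network_module`.
#' @export
max_scoring_subnetwork <- function(net, method = c("auto", "exact", "heuristic"),
                                   allow_empty = FALSE, exact_limit = 30L) {
  method <- match.arg(method)
  stopifnot(inherits(net, "scored_network"))
  g <- net$graph
  scores <- net$scores
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  if (igraph::components(g)$no != 1L)
    stop("network must be a single connected component (use scored_network())",
         call. = FALSE)

  if (all(scores <= 0) && allow_empty)
    return(new_module(character(0), g, scores, method))

  if (method != "heuristic") {
    gc <- reduce_positive(g, scores)
    nc <- igraph::vcount(gc)
    if (nc <= exact_limit) {
      adj <- lapply(igraph::as_adj_list(gc), as.integer)
      res <- exact_best_connected(adj, igraph::V(gc)$score)
      nodes <- unlist(strsplit(igraph::V(gc)$name[res$set], "|", fixed = TRUE))
      if (res$score < 0 && allow_empty)
        return(new_module(character(0), g, scores, "exact"))
      return(new_module(nodes, g, scores, "exact"))
    }
    if (method == "exact")
      stop(sprintf("reduced graph has %d nodes (> exact_limit = %d); use the heuristic",
                   nc, exact_limit), call. = FALSE)
  }
  heuristic_module(g, scores, allow_empty)
}

heuristic_module <- function(g, scores, allow_empty = FALSE) {
  pos <- names(scores)[scores > 0]
  if (length(pos) == 0L) {
    if (allow_empty) return(new_module(character(0), g, scores, "heuristic"))
    return(new_module(names(which.max(scores)), g, scores, "heuristic"))
  }
  sub <- igraph::induced_subgraph(g, pos)
  comp <- igraph::components(sub)
  comps <- split(igraph::V(sub)$name, comp$membership)
  comp_scores <- vapply(comps, function(v) sum(scores[v]), numeric(1))

  if (igraph::ecount(g) == 0L)
    return(new_module(comps[[which.max(comp_scores)]][1], g, scores,
                      "heuristic"))

  # directed arcs priced by the cost of entering the target vertex
  el <- igraph::as_edgelist(g)
  cost <- pmax(-scores, 0)  # entering vertex v costs max(0, -score(v))
  arcs <- rbind(el, el[, 2:1, drop = FALSE])
  w <- cost[arcs[, 2]]
  gd <- igraph::graph_from_edgelist(arcs, directed = TRUE)
  igraph::E(gd)$weight <- w
  # vertex order in gd follows first appearance; map names
  module <- comps[[which.max(comp_scores)]]
  remaining <- setdiff(seq_along(comps), which.max(comp_scores))

  repeat {
    if (length(remaining) == 0L) break
    dmat <- igraph::distances(gd, v = module,
                              to = unlist(comps[remaining]),
                              mode = "out")
    # best gain over remaining components
    best_gain <- 0; best <- NULL
    for (ci in remaining) {
      cols <- intersect(colnames(dmat), comps[[ci]])
      d <- dmat[, cols, drop = FALSE]
      gain <- comp_scores[[as.character(ci)]] - min(d)
      if (gain > best_gain + 1e-12) {
        hit <- which(d == min(d), arr.ind = TRUE)[1, ]
        best_gain <- gain
        best <- list(ci = ci, from = rownames(d)[hit[1]],
                     to = cols[hit[2]])
      }
    }
    if (is.null(best)) break
    path <- igraph::shortest_paths(gd, from = best$from, to = best$to,
                                   mode = "out", output = "vpath")$vpath[[1]]
    module <- union(module, c(names(path), comps[[best$ci]]))
    remaining <- setdiff(remaining, best$ci)
  }

  # prune negative-score leaves of the module's induced subgraph
  # (removing a degree-1 vertex can never disconnect the module)
  repeat {
    if (length(module) <= 1L) break
    ms <- igraph::induced_subgraph(g, module)
    degs <- igraph::degree(ms)
    drop <- names(degs)[degs == 1 & scores[names(degs)] < 0]
    if (length(drop) == 0L) break
    module <- setdiff(module, drop)
  }
  new_module(module, g, scores, "heuristic")
}
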