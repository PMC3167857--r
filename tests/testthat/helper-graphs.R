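# Shared fixture builders and small independent oracles, all in plain base R
# (no package internals) so they stay independent of the code under test.

# Named undirected graph from a vector of node pairs c("A","B", "B","C", ...)
g_from_pairs <- function(pairs) {
  igraph::make_graph(pairs, directed = FALSE)
}

path4 <- function() g_from_pairs(c("A","B", "B","C", "C","D"))

# Random connected graph with `n` named nodes: Erdos-Renyi conditioned on
# connectivity by adding a random spanning tree.
random_connected_graph <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  el <- pairs[keep, , drop = FALSE]
  perm <- sample(n)
  tree_edges <- cbind(perm[-n], perm[-1L])
  el <- rbind(el, tree_edges)
  g <- igraph::graph_from_edgelist(matrix(nodes[el], ncol = 2L),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  g
}

# Hand-rolled reachability (BFS on an edge list) for cross-checking
# connectivity and components without igraph.
bfs_component <- function(nodes, edges, start) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- unique(c(edges[edges[, 1L] %in% frontier, 2L],
                    edges[edges[, 2L] %in% frontier, 1L]))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

brute_components <- function(nodes, edges) {
  left <- nodes
  comps <- list()
  while (length(left) > 0L) {
    comp <- bfs_component(nodes, edges, left[1L])
    comps[[length(comps) + 1L]] <- comp
    left <- setdiff(left, comp)
  }
  comps
}

# All-pairs shortest path lengths by Floyd-Warshall, for metric checks.
brute_distances <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    d[el[r, 1L], el[r, 2L]] <- 1
    d[el[r, 2L], el[r, 1L]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Expected module-interaction set at a level, derived directly from the
# original edge list and the node -> module assignment (brute force; the
# implementation instead projects edges level by level).
brute_module_edges <- function(g, partition) {
  el <- igraph::as_edgelist(g, names = TRUE)
  a <- partition[el[, 1L]]
  b <- partition[el[, 2L]]
  keep <- a != b
  m <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  m <- unique(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# background of N with the first K marked, and count draws with >= k marks.
brute_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Representatives of all isomorphism classes of connected graphs on
# 2..max_n labelled vertices, enumerated by edge subsets and reduced with a
# canonical labelling. Vertices are named "a", "b", ...
connected_graph_reps <- function(max_n = 6L) {
  reps <- list()
  for (n in 2:max_n) {
    pairs <- t(combn(n, 2L))
    np <- nrow(pairs)
    seen <- new.env(hash = TRUE)
    for (mask in seq_len(2^np) - 1L) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(np) - 1L)) != 0L)
      if (length(sel) < n - 1L) next  # cannot be connected
      g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE],
                                       directed = FALSE)
      if (igraph::vcount(g) < n) g <- g + igraph::vertices(seq_len(n))
      if (igraph::components(g)$no > 1L) next
      cp <- igraph::canonical_permutation(g)$labeling
      gc <- igraph::permute(g, cp)
      el <- igraph::as_edgelist(gc, names = FALSE)
      el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
      el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
      key <- paste(n, paste(t(el), collapse = ","))
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        igraph::V(g)$name <- letters[seq_len(n)]
        reps[[length(reps) + 1L]] <- g
      }
    }
  }
  reps
}
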