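#' Jaccard index of two identifier sets
#'
#' `|A intersect B| / |A union B|`, the neighborhood-similarity score used to
#' drive module merging: 0 when the sets share no element, 1 when they are
#' identical. Defined as 0 when both sets are empty. Inputs are treated as
#' sets (duplicates ignored).
#'
#' Internally, merge decisions never compare floating-point quotients:
#' similarities are held as integer (intersection, union) pairs and compared
#' by cross-multiplication, so ties are exact on every platform. This
#' function is the user-facing numeric view of that quantity.
#'
#' @param na,nb character (or atomic) vectors interpreted as sets.
#' @return a number in `[0, 1]`.
#' @examples
#' jaccard_similarity(c("B"), c("B", "D"))  # 0.5
#' @export
jaccard_similarity <- function(na, nb) {
  na <- unique(na); nb <- unique(nb)
  u <- length(union(na, nb))
  if (u == 0L) return(0)
  length(intersect(na, nb)) / u
}

#' Neighborhood of a module in the original network
#'
#' The union of the interaction partners of a module's members, taken in the
#' original protein network. With the default `mode = "inclusive"`, members
#' that are themselves partners of other members stay in the set, so two
#' densely connected halves of the same functional module keep strongly
#' overlapping neighborhoods and are drawn back together as the hierarchy
#' grows — the behaviour of topological-overlap-style similarity measures.
#' `mode = "exclusive"` removes the module's own members, scoring only
#' shared *external* context; it makes the complementary halves of a dense
#' module look maximally dissimilar (each half's neighborhood is the other
#' half), which stalls module reassembly at coarse levels, and is provided
#' for comparison. For singleton modules in a simple graph the two modes
#' coincide, so protein-level (level-1) similarities are unaffected.
#'
#' @param members character vector of protein identifiers forming the module.
#' @param net the original network (igraph, simple, undirected, named).
#' @param mode `"inclusive"` (default) or `"exclusive"`.
#' @return sorted character vector of neighbor identifiers.
#' @examples
#' g <- igraph::make_graph(c("A","B", "B","C", "C","D"), directed = FALSE)
#' module_neighborhood(c("A", "B"), g, mode = "exclusive")  # "C"
#' module_neighborhood(c("A", "B"), g)                      # "A" "B" "C"
#' @export
module_neighborhood <- function(members, net,
                                mode = c("inclusive", "exclusive")) {
  mode <- match.arg(mode)
  check_network(net)
  idx <- match(members, igraph::V(net)$name)
  if (anyNA(idx))
    stop("module member(s) not in network: ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  nb <- unique(unlist(igraph::adjacent_vertices(net, idx), use.names = FALSE))
  nb <- igraph::V(net)$name[nb]
  if (mode == "exclusive") nb <- setdiff(nb, members)
  sort(nb)
}

# ---- internal machinery -----------------------------------------------------

# Integer neighborhood index sets for a list of modules (index space = vertex
# order of `net`'s adjacency list `adj`).
neighborhood_sets <- function(memb_idx, adj, mode) {
  lapply(memb_idx, function(m) {
    nb <- unique(unlist(adj[m], use.names = FALSE))
    if (mode == "exclusive") nb <- setdiff(nb, m)
    nb
  })
}

# All-pairs intersection and union sizes of integer sets over 1..n, via a
# sparse incidence matrix. Returns list(inter, union_) of k x k matrices.
pairwise_set_counts <- function(sets, n) {
  k <- length(sets)
  len <- lengths(sets)
  M <- Matrix::sparseMatrix(i = rep.int(seq_len(k), len),
                            j = unlist(sets, use.names = FALSE),
                            x = 1, dims = c(k, n))
  inter <- as.matrix(Matrix::tcrossprod(M))
  list(inter = inter, union_ = outer(len, len, "+") - inter)
}

# Find the pairs attaining the exact maximum rational inter/union among the
# upper-triangle pairs. Candidates are pre-screened by the floating quotient
# (equal rationals round to identical doubles; correctly rounded division is
# monotone, so no true maximum escapes the screen) and then verified by
# integer cross-multiplication. Returns list(pairs = m x 2 index matrix,
# num, den) with num/den the maximal similarity; den == 0 encodes s* = 0
# only when every pair is 0/0 (both neighborhoods empty).
max_similarity_pairs <- function(inter, union_) {
  k <- nrow(inter)
  ut <- upper.tri(inter)
  val <- matrix(0, k, k)
  pos <- ut & union_ > 0
  val[pos] <- inter[pos] / union_[pos]
  m <- max(val[ut])
  if (m == 0)
    return(list(pairs = which(ut, arr.ind = TRUE), num = 0, den = 1))
  cand <- which(ut & val == m, arr.ind = TRUE)
  ci <- inter[cand]; cu <- union_[cand]
  # exact maximum among candidates
  bi <- ci[1L]; bu <- cu[1L]
  for (j in seq_along(ci)) {
    if (ci[j] * bu > bi * cu[j]) { bi <- ci[j]; bu <- cu[j] }
  }
  keep <- ci * bu == bi * cu
  list(pairs = cand[keep, , drop = FALSE], num = bi, den = bu)
}

# Connected components of the graph on 1..k induced by `pairs` (m x 2).
# Plain union-find; returns a component label per vertex.
pair_components <- function(k, pairs) {
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs) > 0L)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[a] <- b
    }
  vapply(seq_len(k), find, 0L)
}

new_hierarchy <- function(level, ids, members, children, edges) {
  structure(list(level = level, ids = as.integer(ids), members = members,
                 children = children, edges = edges),
            class = "module_hierarchy")
}

#' @export
print.module_hierarchy <- function(x, ...) {
  cat("Hierarchy level ", x$level, ": ", length(x$ids), " module(s), ",
      nrow(x$edges), " module interaction(s)\n", sep = "")
  invisible(x)
}

#' One agglomeration step: merge the maximally similar modules
#'
#' Advances a hierarchy by one level. All pairwise module neighborhood
#' similarities are computed against the original network; the exact maximum
#' `s*` is found by integer cross-multiplication (no floating-point ties);
#' every connected component of the graph formed by the pairs attaining `s*`
#' becomes one merged module (so a module tied with several partners merges
#' with all of them, giving modules with two or more children); all other
#' modules are carried forward unchanged. When `s* = 0` no ordering
#' information remains and all modules merge into the single root. Module
#' interactions are re-derived so that two modules interact at the new level
#' if and only if some protein in one interacts with some protein in the
#' other in the original network.
#'
#' New module identifiers are assigned sequentially from `next_id` in order
#' of each merged module's lexicographically smallest member; carried-forward
#' modules keep their identifier.
#'
#' @param h a `module_hierarchy` (one level of a [module_tree][build_tree]).
#' @param net the original protein network.
#' @param neighborhood `"inclusive"` (default) or `"exclusive"`, see
#'   [module_neighborhood()].
#' @param next_id first identifier for newly merged modules; defaults to
#'   `max(h$ids) + 1`.
#' @return the next `module_hierarchy`, with attribute `"s_star"` holding the
#'   maximal similarity as an integer `c(numerator, denominator)` pair.
#' @export
merge_step <- function(h, net, neighborhood = c("inclusive", "exclusive"),
                       next_id = NULL) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(inherits(h, "module_hierarchy"))
  check_network(net)
  k <- length(h$ids)
  if (k < 2L)
    stop("cannot merge a single-module hierarchy", call. = FALSE)
  if (is.null(next_id)) next_id <- max(h$ids) + 1L
  vnames <- igraph::V(net)$name
  adj <- adjacency_index_list(net)
  memb_idx <- lapply(h$members, function(m) {
    i <- match(m, vnames)
    if (anyNA(i))
      stop("module member(s) not in network: ",
           paste(m[is.na(i)], collapse = ", "), call. = FALSE)
    sort.int(i)
  })

  nb <- neighborhood_sets(memb_idx, adj, neighborhood)
  cnt <- pairwise_set_counts(nb, length(vnames))
  mx <- max_similarity_pairs(cnt$inter, cnt$union_)

  comp <- pair_components(k, mx$pairs)
  groups <- unname(split(seq_len(k), comp))
  merged <- groups[lengths(groups) >= 2L]
  carried <- sort(unlist(groups[lengths(groups) == 1L], use.names = FALSE))

  # order merged modules by their smallest member identifier
  if (length(merged) > 0L) {
    smallest <- vapply(merged, function(g)
      min(unlist(h$members[g], use.names = FALSE)), "")
    merged <- merged[order(smallest)]
  }
  new_ids <- if (length(merged) > 0L)
    seq.int(next_id, length.out = length(merged)) else integer(0)

  parent <- integer(k)  # position in h -> id at the new level
  parent[carried] <- h$ids[carried]
  for (j in seq_along(merged)) parent[merged[[j]]] <- new_ids[j]

  ids2 <- c(h$ids[carried], new_ids)
  members2 <- c(h$members[carried],
                lapply(merged, function(g)
                  sort(unique(unlist(h$members[g], use.names = FALSE)))))
  children2 <- c(as.list(h$ids[carried]),
                 lapply(merged, function(g) sort(h$ids[g])))
  o <- order(ids2)
  ids2 <- ids2[o]; members2 <- members2[o]; children2 <- children2[o]
  children2 <- lapply(children2, as.integer)

  # project module interactions through the parent map
  pos <- match(h$edges, h$ids)  # works columnwise on the matrix
  edges2 <- canonical_edges(matrix(parent[pos], ncol = 2L))

  out <- new_hierarchy(h$level + 1L, ids2, members2, children2, edges2)
  attr(out, "s_star") <- c(mx$num, mx$den)
  out
}

#' Build the hierarchical module tree of a protein network
#'
#' Agglomeratively clusters a connected protein network into a hierarchical
#' tree of modules. Level 1 holds one singleton module per protein, with
#' module interactions mirroring the protein interactions. Each subsequent
#' level is produced by [merge_step()]: the module pairs with the exact
#' maximal Jaccard neighborhood similarity are merged (connected components
#' of the tie graph), everything else is carried forward, and module
#' interactions are re-derived losslessly. The process repeats until a single
#' root module remains.
#'
#' The representation is lossless: at every level, two modules interact if
#' and only if some member of one interacts with some member of the other in
#' the input network, so each level is a coarse-grained but faithful view of
#' the original connectivity.
#'
#' @param net a connected simple undirected igraph with protein identifiers
#'   as vertex names (pass the output of [largest_connected_component()]).
#' @param neighborhood module-neighborhood convention, see
#'   [module_neighborhood()].
#' @return an object of class `module_tree`: a list with elements `nodes`
#'   (sorted identifiers), `graph` (the input network, vertices in sorted
#'   order), `neighborhood`, `levels` (list of `module_hierarchy`), and
#'   `n_levels`.
#' @examples
#' g <- igraph::make_graph(c("A","B", "B","C", "C","D"), directed = FALSE)
#' tr <- build_tree(g)
#' tr            # 3 levels: singletons; {A,C},{B,D}; root
#' @export
build_tree <- function(net, neighborhood = c("inclusive", "exclusive")) {
  neighborhood <- match.arg(neighborhood)
  check_network(net)
  n <- igraph::vcount(net)
  if (n < 2L)
    stop("need a network with at least 2 proteins", call. = FALSE)
  ncomp <- igraph::components(net)$no
  if (ncomp > 1L)
    stop("network is disconnected (", ncomp, " components); pass the ",
         "largest connected component", call. = FALSE)
  if (n > 20000L)
    warning("network has ", n, " proteins; tree construction will be slow",
            call. = FALSE)
  nodes <- sort(igraph::V(net)$name)
  g <- igraph::permute(net, match(igraph::V(net)$name, nodes))

  el <- matrix(match(igraph::as_edgelist(g, names = TRUE), nodes), ncol = 2L)
  h <- new_hierarchy(1L, seq_len(n), as.list(nodes),
                     rep(list(integer(0)), n), canonical_edges(el))
  levels <- list(h)
  next_id <- n + 1L
  while (length(h$ids) > 1L) {
    h <- merge_step(h, g, neighborhood, next_id)
    next_id <- max(next_id, max(h$ids) + 1L)
    levels[[length(levels) + 1L]] <- h
  }
  tree <- structure(list(nodes = nodes, graph = g,
                         neighborhood = neighborhood, levels = levels,
                         n_levels = length(levels)),
                    class = "module_tree")
  validate_tree(tree)
  tree
}

#' Module assignment of every protein at one level
#'
#' @param tree a [module_tree][build_tree].
#' @param level hierarchy level (1 = singletons).
#' @return named integer vector mapping each protein to its module id.
#' @export
level_partition <- function(tree, level) {
  stopifnot(inherits(tree, "module_tree"))
  if (level < 1L || level > tree$n_levels)
    stop("level must be in 1..", tree$n_levels, call. = FALSE)
  h <- tree$levels[[level]]
  out <- rep.int(h$ids, lengths(h$members))
  names(out) <- unlist(h$members, use.names = FALSE)
  out[tree$nodes]
}

#' Flat membership table of a module tree
#'
#' @param tree a [module_tree][build_tree].
#' @return a data.frame with columns `module_id`, `level`, `member`, one row
#'   per (module, member) pair — the spreadsheet-friendly export.
#' @export
tree_membership <- function(tree) {
  stopifnot(inherits(tree, "module_tree"))
  do.call(rbind, lapply(tree$levels, function(h) {
    data.frame(module_id = rep.int(h$ids, lengths(h$members)),
               level = h$level,
               member = unlist(h$members, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
}

# Structural invariant checks; stops on the first violation.
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "module_tree"))
  nodes <- tree$nodes
  n <- length(nodes)
  L <- tree$n_levels
  if (L != length(tree$levels)) stop("n_levels mismatch", call. = FALSE)
  prev <- NULL
  for (h in tree$levels) {
    all_members <- unlist(h$members, use.names = FALSE)
    if (length(all_members) != n || anyDuplicated(all_members) ||
        !setequal(all_members, nodes))
      stop("level ", h$level, ": modules do not partition the protein set",
           call. = FALSE)
    if (anyDuplicated(h$ids))
      stop("level ", h$level, ": duplicate module ids", call. = FALSE)
    if (nrow(h$edges) > 0L &&
        (!all(h$edges %in% h$ids) || any(h$edges[, 1L] == h$edges[, 2L])))
      stop("level ", h$level, ": invalid module interaction", call. = FALSE)
    if (h$level == 1L) {
      if (any(lengths(h$members) != 1L) || any(lengths(h$children) != 0L))
        stop("level 1 must consist of childless singletons", call. = FALSE)
    } else {
      if (length(h$ids) >= length(prev$ids))
        stop("module count must strictly decrease (level ", h$level, ")",
             call. = FALSE)
      for (j in seq_along(h$ids)) {
        ch <- h$children[[j]]
        if (length(ch) == 0L || !all(ch %in% prev$ids))
          stop("level ", h$level, ": bad children for module ", h$ids[j],
               call. = FALSE)
        ch_members <- sort(unique(unlist(prev$members[match(ch, prev$ids)],
                                         use.names = FALSE)))
        if (!identical(ch_members, h$members[[j]]))
          stop("level ", h$level, ": module ", h$ids[j],
               " members differ from union of children", call. = FALSE)
        if (length(ch) == 1L && ch != h$ids[j])
          stop("level ", h$level, ": carried module ", h$ids[j],
               " changed identifier", call. = FALSE)
      }
    }
    prev <- h
  }
  if (length(tree$levels[[1L]]$ids) != n ||
      length(tree$levels[[L]]$ids) != 1L)
    stop("tree must run from ", n, " singletons to a single root",
         call. = FALSE)
  # level-1 interactions must mirror the network exactly (losslessness base)
  if (!is.null(tree$graph)) {
    el <- matrix(match(igraph::as_edgelist(tree$graph, names = TRUE), nodes),
                 ncol = 2L)
    if (!identical(canonical_edges(el), tree$levels[[1L]]$edges))
      stop("level-1 module interactions do not mirror the network",
           call. = FALSE)
  }
  invisible(tree)
}

#' @export
print.module_tree <- function(x, ...) {
  cat("Hierarchical module tree\n")
  cat("  proteins:    ", length(x$nodes), "\n", sep = "")
  cat("  interactions:", igraph::gsize(x$graph), "\n", sep = " ")
  cat("  hierarchies: ", x$n_levels, "\n", sep = "")
  cat("  neighborhood:", x$neighborhood, "\n", sep = " ")
  counts <- vapply(x$levels, function(h) length(h$ids), 0L)
  cat("  modules per level: ", paste(counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.module_tree <- function(object, ...) {
  counts <- vapply(object$levels, function(h) length(h$ids), 0L)
  edges <- vapply(object$levels, function(h) nrow(h$edges), 0L)
  s_star <- t(vapply(object$levels, function(h) {
    s <- attr(h, "s_star")
    if (is.null(s)) c(NA_real_, NA_real_) else as.numeric(s)
  }, numeric(2)))
  df <- data.frame(level = seq_along(counts), n_modules = counts,
                   n_module_edges = edges,
                   merge_similarity = s_star[, 1L] / s_star[, 2L])
  structure(list(table = df, n_nodes = length(object$nodes),
                 neighborhood = object$neighborhood),
            class = "summary.module_tree")
}

#' @export
print.summary.module_tree <- function(x, ...) {
  cat("Hierarchical module tree on", x$n_nodes, "proteins (",
      x$neighborhood, "neighborhoods )\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @describeIn build_tree plot module count (and module-interaction count)
#'   against hierarchy level.
#' @param x a `module_tree`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.module_tree <- function(x, ...) {
  counts <- vapply(x$levels, function(h) length(h$ids), 0L)
  edges <- vapply(x$levels, function(h) nrow(h$edges), 0L)
  plot(seq_along(counts), counts, type = "b", pch = 16,
       xlab = "hierarchy level", ylab = "count",
       ylim = c(0, max(counts, edges)), ...)
  lines(seq_along(edges), edges, type = "b", pch = 1, lty = 2)
  legend("topright", legend = c("modules", "module interactions"),
         pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
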