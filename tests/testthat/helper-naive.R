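# Naive reference implementation of the hierarchical merge and the pathway
# search: plain lists, loops, BFS, and exact fraction comparison by
# cross-multiplication. Everything is recomputed from scratch at every level
# straight from the original edge list. Deliberately shares no code with the
# package implementation.

naive_neighborhood <- function(members, el, mode) {
  nb <- character(0)
  for (p in members) {
    nb <- c(nb, el[el[, 1L] == p, 2L], el[el[, 2L] == p, 1L])
  }
  nb <- unique(nb)
  if (mode == "exclusive") nb <- setdiff(nb, members)
  sort(nb)
}

# similarity as an exact fraction c(numerator, denominator)
naive_jaccard_frac <- function(a, b) {
  u <- length(unique(c(a, b)))
  if (u == 0L) return(c(0L, 1L))
  c(sum(a %in% b), u)
}

frac_gt <- function(x, y) x[1L] * y[2L] > y[1L] * x[2L]
frac_eq <- function(x, y) x[1L] * y[2L] == y[1L] * x[2L]

# modules: named list id -> member character vector
naive_module_edges <- function(modules, el) {
  ids <- as.integer(names(modules))
  out <- matrix(integer(0), ncol = 2L)
  if (length(ids) < 2L) return(out)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    cross <- any((el[, 1L] %in% modules[[i]] & el[, 2L] %in% modules[[j]]) |
                 (el[, 2L] %in% modules[[i]] & el[, 1L] %in% modules[[j]]))
    if (cross) out <- rbind(out, c(min(ids[i], ids[j]), max(ids[i], ids[j])))
  }
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# Returns a list of levels; each level is list(ids, members (named list),
# children (named list)) plus edges. Mirrors the merge rule: exact maximal
# similarity, connected components of the tie graph, s* = 0 => full merge.
naive_build_tree <- function(g, mode = "inclusive") {
  el <- igraph::as_edgelist(g, names = TRUE)
  nodes <- sort(igraph::V(g)$name)
  modules <- as.list(nodes)
  names(modules) <- seq_along(nodes)
  levels <- list(list(modules = modules,
                      children = setNames(rep(list(integer(0)),
                                              length(nodes)),
                                          names(modules)),
                      edges = naive_module_edges(modules, el)))
  next_id <- length(nodes) + 1L
  while (length(modules) > 1L) {
    ids <- as.integer(names(modules))
    k <- length(ids)
    nbs <- lapply(modules, naive_neighborhood, el = el, mode = mode)
    # all pair fractions; track exact maximum
    best <- c(0L, 1L)
    fracs <- list()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      f <- naive_jaccard_frac(nbs[[i]], nbs[[j]])
      fracs[[paste(i, j)]] <- f
      if (frac_gt(f, best)) best <- f
    }
    if (best[1L] == 0L) {
      pairs <- t(combn(k, 2L))           # merge everything into the root
    } else {
      pairs <- do.call(rbind, lapply(names(fracs), function(nm) {
        if (frac_eq(fracs[[nm]], best))
          as.integer(strsplit(nm, " ")[[1L]])
      }))
    }
    # components of the tie graph by BFS
    labels <- rep(NA_integer_, k)
    comp <- 0L
    for (s in seq_len(k)) {
      if (!is.na(labels[s])) next
      comp <- comp + 1L
      frontier <- s
      labels[s] <- comp
      while (length(frontier) > 0L) {
        adj <- unique(c(pairs[pairs[, 1L] %in% frontier, 2L],
                        pairs[pairs[, 2L] %in% frontier, 1L]))
        frontier <- adj[is.na(labels[adj])]
        labels[frontier] <- comp
      }
    }
    new_modules <- list(); new_children <- list()
    merged_pos <- which(tabulate(labels)[labels] >= 2L)
    carried_pos <- setdiff(seq_len(k), merged_pos)
    for (p in carried_pos) {
      new_modules[[as.character(ids[p])]] <- modules[[p]]
      new_children[[as.character(ids[p])]] <- ids[p]
    }
    groups <- unique(labels[merged_pos])
    if (length(groups) > 0L) {
      mins <- vapply(groups, function(gr)
        min(unlist(modules[labels == gr])), "")
      groups <- groups[order(mins)]
      for (gr in groups) {
        sel <- which(labels == gr)
        new_modules[[as.character(next_id)]] <-
          sort(unique(unlist(modules[sel])))
        new_children[[as.character(next_id)]] <- sort(ids[sel])
        next_id <- next_id + 1L
      }
    }
    ord <- order(as.integer(names(new_modules)))
    modules <- new_modules[ord]
    levels[[length(levels) + 1L]] <-
      list(modules = modules, children = new_children[ord],
           edges = naive_module_edges(modules, el))
  }
  levels
}

# Naive bottom-up pathway search over a naive tree: first level whose
# disease-containing modules are mutually reachable through module edges.
naive_search_pathway <- function(naive_levels, disease) {
  for (lv in seq_along(naive_levels)) {
    L <- naive_levels[[lv]]
    risk <- as.integer(names(L$modules))[vapply(L$modules, function(m)
      any(disease %in% m), NA)]
    e <- L$edges
    e <- e[e[, 1L] %in% risk & e[, 2L] %in% risk, , drop = FALSE]
    comp <- brute_components(risk, e)
    if (length(comp) == 1L)
      return(list(level = lv, risk = sort(risk), edges = e))
  }
  stop("unreachable")
}

# Boolean structural comparison of a package module_tree with a naive tree.
tree_matches_naive <- function(tree, naive_levels) {
  if (tree$n_levels != length(naive_levels)) return(FALSE)
  for (lv in seq_len(tree$n_levels)) {
    h <- tree$levels[[lv]]
    L <- naive_levels[[lv]]
    ne <- L$edges
    dimnames(ne) <- NULL
    storage.mode(ne) <- "integer"
    if (!identical(h$ids, as.integer(names(L$modules))) ||
        !identical(h$members, unname(L$modules)) ||
        !identical(unname(h$edges), ne))
      return(FALSE)
    if (lv > 1L &&
        !identical(h$children, lapply(unname(L$children), as.integer)))
      return(FALSE)
  }
  TRUE
}

# Compare a package module_tree with a naive tree structurally.
expect_tree_equals_naive <- function(tree, naive_levels) {
  expect_equal(tree$n_levels, length(naive_levels))
  for (lv in seq_len(tree$n_levels)) {
    h <- tree$levels[[lv]]
    L <- naive_levels[[lv]]
    expect_identical(h$ids, as.integer(names(L$modules)))
    expect_identical(h$members, unname(L$modules))
    if (lv > 1L)
      expect_identical(h$children,
                       lapply(unname(L$children), as.integer))
    ne <- L$edges
    dimnames(ne) <- NULL
    storage.mode(ne) <- "integer"
    expect_identical(unname(h$edges), ne)
  }
}
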