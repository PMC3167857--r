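# Tree serialization: a versioned JSON schema with sorted members and edges
# so that identical trees produce byte-identical files.

TREE_FORMAT_VERSION <- "1.0"

#' Serialize / deserialize a module tree
#'
#' `serialize_tree()` writes a [module_tree][build_tree] as JSON with schema
#' `{version, neighborhood, nodes, levels:[{level, modules:[{id, members,
#' children}], edges:[[id,id],...]}]}`. Members and edges are emitted sorted,
#' so equal trees serialize byte-identically. `deserialize_tree()` reads the
#' file back, reconstructs the underlying network from the level-1 module
#' interactions (which mirror it exactly), and re-validates every structural
#' invariant, so a hand-edited file that breaks the partition property is
#' rejected.
#'
#' @param tree a `module_tree`.
#' @param path file path.
#' @return `serialize_tree()` returns `path` invisibly; `deserialize_tree()`
#'   returns a validated `module_tree`.
#' @export
serialize_tree <- function(tree, path) {
  stopifnot(inherits(tree, "module_tree"))
  obj <- list(
    version = TREE_FORMAT_VERSION,
    neighborhood = tree$neighborhood,
    nodes = tree$nodes,
    levels = lapply(tree$levels, function(h) {
      list(level = h$level,
           modules = lapply(seq_along(h$ids), function(j)
             list(id = h$ids[j], members = h$members[[j]],
                  children = h$children[[j]])),
           edges = if (nrow(h$edges) > 0L) unname(h$edges)
                   else matrix(integer(0), ncol = 2L))
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  write_lines_atomic(json, path)
}

#' @rdname serialize_tree
#' @export
deserialize_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupt tree file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$version, TREE_FORMAT_VERSION))
    stop("tree file version mismatch: expected ", TREE_FORMAT_VERSION,
         ", found ", if (is.null(obj$version)) "<none>" else obj$version,
         call. = FALSE)
  nodes <- as.character(unlist(obj$nodes))
  levels <- lapply(obj$levels, function(lv) {
    ids <- vapply(lv$modules, function(m) as.integer(m$id), 0L)
    members <- lapply(lv$modules, function(m)
      as.character(unlist(m$members)))
    children <- lapply(lv$modules, function(m)
      as.integer(unlist(m$children)))
    edges <- if (length(lv$edges) == 0L) matrix(integer(0), ncol = 2L)
             else t(vapply(lv$edges, function(e) as.integer(unlist(e)),
                           integer(2)))
    new_hierarchy(as.integer(lv$level), ids, members, children,
                  canonical_edges(edges))
  })
  # the network is recoverable: level-1 module interactions mirror it
  h1 <- levels[[1L]]
  el <- matrix(nodes[h1$edges], ncol = 2L)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
  g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
  tree <- structure(list(nodes = nodes, graph = g,
                         neighborhood = obj$neighborhood,
                         levels = levels, n_levels = length(levels)),
                    class = "module_tree")
  tryCatch(validate_tree(tree),
           error = function(e)
             stop("invalid tree file ", path, ": ", conditionMessage(e),
                  call. = FALSE))
  tree
}
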