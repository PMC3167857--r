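# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls stay side-effect free.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Canonical "u\tv" keys (u < v lexicographically) for an edge character
# matrix; used for set comparisons of protein-level edges.
edge_keys <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0L) return(character(0))
  a <- pmin(m[, 1L], m[, 2L])
  b <- pmax(m[, 1L], m[, 2L])
  paste(a, b, sep = "\t")
}

# Sort the rows of a 2-column integer edge matrix into canonical order:
# each row ascending, rows ordered lexicographically, duplicates dropped.
canonical_edges <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0L)
    return(matrix(integer(0), ncol = 2L))
  a <- pmin(m[, 1L], m[, 2L])
  b <- pmax(m[, 1L], m[, 2L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(matrix(integer(0), ncol = 2L))
  key <- paste(a, b)
  d <- !duplicated(key)
  a <- a[d]; b <- b[d]
  o <- order(a, b)
  cbind(a[o], b[o])
}

# Assert an igraph object is a usable protein network: named, undirected,
# simple. Called at the entry of every operation taking a network.
check_network <- function(net, arg = "net") {
  if (!igraph::is_igraph(net))
    stop("`", arg, "` must be an igraph object (see read_edge_list())",
         call. = FALSE)
  if (igraph::is_directed(net))
    stop("`", arg, "` must be an undirected network", call. = FALSE)
  if (is.null(igraph::V(net)$name))
    stop("`", arg, "` must have protein identifiers as vertex names",
         call. = FALSE)
  if (igraph::any_loop(net) || igraph::any_multiple(net))
    stop("`", arg, "` must be a simple graph (no self-loops or duplicate ",
         "edges); use igraph::simplify()", call. = FALSE)
  invisible(net)
}

# Adjacency list as integer indices, in vertex order.
adjacency_index_list <- function(net) {
  lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
}

# Write `lines` to `path` atomically (temp file + rename).
write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
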