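#' Read a protein interaction network from an edge list or SIF file
#'
#' Parses a two-column tab/whitespace-separated edge list (one interaction per
#' line) or a SIF file (`node relation node [node ...]`; the relation field is
#' ignored, and a line with several targets yields one edge per target) into a
#' simple undirected network. Duplicate lines and reversed duplicates collapse
#' to a single edge; self-loops are dropped with a message reporting how many.
#' Lines starting with `#` and blank lines are ignored.
#'
#' Identifiers are treated as opaque, case-sensitive strings: no gene-symbol
#' normalisation is attempted, because identifier mapping is specific to the
#' data source.
#'
#' @param path path to the input file.
#' @param format `"tsv"` (default) for a two-column edge list, `"sif"` for
#'   Simple Interaction Format.
#' @return an undirected simple [igraph][igraph::igraph-package] graph whose
#'   vertex names are the protein identifiers.
#' @seealso [write_edge_list()], [largest_connected_component()]
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), f)
#' g <- read_edge_list(f)
#' igraph::gsize(g)   # 2 edges: A-B, B-C
#' @export
read_edge_list <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty edge-list file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  min_fields <- if (format == "sif") 3L else 2L
  bad <- which(nf < min_fields)
  # SIF tolerates isolated-node lines with a single field; an edge list does
  # not have that concept, so any short line is a parse error.
  if (format == "sif") bad <- bad[nf[bad] != 1L]
  if (length(bad) > 0L)
    stop("malformed line ", line_no[bad[1L]], " in ", path, ": expected at ",
         "least ", min_fields, " fields, got ", nf[bad[1L]], call. = FALSE)
  if (format == "tsv") {
    from <- vapply(fields, `[`, "", 1L)
    to   <- vapply(fields, `[`, "", 2L)
    isolated <- character(0)
  } else {
    edge_lines <- fields[nf >= 3L]
    from <- rep(vapply(edge_lines, `[`, "", 1L),
                times = lengths(edge_lines) - 2L)
    to <- unlist(lapply(edge_lines, `[`, -(1:2)), use.names = FALSE)
    isolated <- unlist(fields[nf == 1L], use.names = FALSE)
  }
  loops <- from == to
  if (any(loops))
    message("dropped ", sum(loops), " self-loop(s)")
  from <- from[!loops]; to <- to[!loops]
  nodes <- sort(unique(c(from, to, isolated)))
  if (length(nodes) == 0L)
    stop("no edges remain after dropping self-loops in ", path, call. = FALSE)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
  igraph::simplify(g)
}

#' Write a network as a deduplicated, sorted edge list
#'
#' Emits one `u<TAB>v` line per edge with `u < v` lexicographically, lines
#' sorted, so that output is bit-exact reproducible and diff-friendly.
#' Re-reading the file with [read_edge_list()] restores an identical node and
#' edge set (isolated vertices, which carry no interactions, are not
#' representable in an edge list and are dropped with a message).
#'
#' @param net a simple undirected igraph with vertex names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  check_network(net)
  iso <- sum(igraph::degree(net) == 0L)
  if (iso > 0L)
    message("omitting ", iso, " isolated vertex/vertices from edge list")
  el <- igraph::as_edgelist(net, names = TRUE)
  lines <- sort(edge_keys(el))
  write_lines_atomic(lines, path)
}

#' Extract the largest connected component of a network
#'
#' Returns the induced subgraph on the largest connected component, the usual
#' analysis substrate for interactome studies. Ties on component size are
#' broken by the lexicographically smallest member identifier, so the result
#' is deterministic.
#'
#' @param net a simple undirected igraph with vertex names.
#' @return the induced subgraph on the winning component.
#' @examples
#' g <- igraph::graph_from_edgelist(
#'   cbind(c("A", "B", "X"), c("B", "C", "Y")), directed = FALSE)
#' igraph::vcount(largest_connected_component(g))  # 3
#' @export
largest_connected_component <- function(net) {
  check_network(net)
  if (igraph::vcount(net) == 0L)
    stop("empty network", call. = FALSE)
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest name within each tied component decides
    mins <- vapply(best, function(ci)
      min(igraph::V(net)$name[comp$membership == ci]), "")
    best <- best[order(mins)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Map disease genes onto a network
#'
#' Reads a disease gene list (one identifier per line, `#` comments ignored)
#' or takes a character vector, and partitions the identifiers into those
#' present in the network (`mapped_ids`) and the rest (`unmapped_ids`).
#' Matching is by exact identifier. Counts are reported via [message()].
#'
#' @param ids path to a gene-list file, or a character vector of identifiers.
#' @param net the network (typically the largest connected component) to map
#'   against.
#' @return an object of class `disease_gene_set`: a list with elements
#'   `raw_ids`, `mapped_ids`, `unmapped_ids` (each a sorted character vector).
#' @examples
#' g <- igraph::make_graph(c("A", "B", "B", "C"), directed = FALSE)
#' map_disease_genes(c("A", "Z"), g)
#' @export
map_disease_genes <- function(ids, net) {
  check_network(net)
  if (length(ids) == 1L && file.exists(ids)) {
    lines <- readLines(ids, warn = FALSE)
    lines <- trimws(lines)
    ids <- lines[!grepl("^(#|$)", lines)]
  }
  ids <- unique(as.character(ids))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L)
    stop("empty disease gene list", call. = FALSE)
  nodes <- igraph::V(net)$name
  mapped <- sort(intersect(ids, nodes))
  if (length(mapped) == 0L)
    stop("zero disease genes mapped onto the network; pathway search ",
         "is impossible", call. = FALSE)
  unmapped <- sort(setdiff(ids, nodes))
  message(length(mapped), " disease gene(s) mapped, ",
          length(unmapped), " unmapped")
  structure(list(raw_ids = sort(ids), mapped_ids = mapped,
                 unmapped_ids = unmapped),
            class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  cat("Disease gene set: ", length(x$raw_ids), " identifiers, ",
      length(x$mapped_ids), " mapped to the network, ",
      length(x$unmapped_ids), " unmapped\n", sep = "")
  cat("  mapped: ", paste(head(x$mapped_ids, 10L), collapse = ", "),
      if (length(x$mapped_ids) > 10L) ", ...", "\n", sep = "")
  invisible(x)
}
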