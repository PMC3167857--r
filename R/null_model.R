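#' Degree-preserving network randomization
#'
#' Randomizes a network by repeated double-edge swaps — pick interactions
#' `(a,b)` and `(c,d)`, replace them with `(a,d)` and `(c,b)` — rejecting
#' swaps that would create self-loops or duplicate edges. Every protein keeps
#' exactly its original degree; only the wiring is destroyed. This is the
#' standard degree-preserving null model for interactome analyses.
#'
#' @param net a simple undirected igraph with vertex names.
#' @param seed integer seed; the same seed and input always give the same
#'   rewired network. The caller's RNG state is untouched.
#' @param swaps_per_edge attempted swaps per edge (default 10; total
#'   attempts = `swaps_per_edge * |edges|`).
#' @return a rewired igraph with an identical degree for every vertex. If
#'   the network has fewer than 2 edges no swap is possible and the input is
#'   returned unchanged with a warning.
#' @export
rewire_degree_preserving <- function(net, seed, swaps_per_edge = 10) {
  check_network(net)
  m <- igraph::gsize(net)
  if (m < 2L) {
    warning("no valid double-edge swap exists; returning input unchanged",
            call. = FALSE)
    return(net)
  }
  # keeping_degseq() rejects swaps creating duplicate edges by construction
  with_seed(seed, igraph::rewire(
    net, igraph::keeping_degseq(loops = FALSE,
                                niter = ceiling(swaps_per_edge * m))))
}

#' Topological metrics of a connected graph
#'
#' Computes the vertex count, diameter (longest shortest path, in edges),
#' characteristic path length (mean shortest-path distance over all vertex
#' pairs), and mean local clustering coefficient (vertices of degree < 2
#' count as 0). A single-vertex graph returns 0 for the last three by
#' convention; a disconnected graph is an error, since these metrics are
#' intended for pathway graphs, which are connected by construction.
#'
#' @param g an igraph, or a [disease_pathway][search_pathway] (its module
#'   graph is used).
#' @return a list of class `network_metrics` with elements `n_vertices`,
#'   `diameter`, `characteristic_path_length`, `clustering_coefficient`.
#' @examples
#' compute_network_metrics(igraph::make_full_graph(3))  # 1, 1, 1
#' @export
compute_network_metrics <- function(g) {
  if (inherits(g, "disease_pathway")) g <- pathway_module_graph(g)
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph", call. = FALSE)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph", call. = FALSE)
  if (igraph::components(g)$no > 1L)
    stop("graph is disconnected; metrics are defined on connected pathway ",
         "graphs", call. = FALSE)
  if (n == 1L) {
    out <- list(n_vertices = 1L, diameter = 0,
                characteristic_path_length = 0, clustering_coefficient = 0)
  } else {
    out <- list(
      n_vertices = n,
      diameter = igraph::diameter(g, unconnected = FALSE),
      characteristic_path_length = igraph::mean_distance(g),
      clustering_coefficient =
        igraph::transitivity(g, type = "localaverage", isolates = "zero"))
  }
  structure(out, class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("vertices: ", x$n_vertices,
      "  diameter: ", x$diameter,
      "  char. path length: ", round(x$characteristic_path_length, 4),
      "  clustering: ", round(x$clustering_coefficient, 4), "\n", sep = "")
  invisible(x)
}

#' Overlap between two disease pathways
#'
#' Compares the pathway found in one network with the pathway found in
#' another (typically a degree-preserving rewiring). Proteins are compared
#' as the union of risk-module members; interactions are compared at the
#' protein level — the original-network edges supporting each module
#' interaction — because module identities are not comparable across
#' networks.
#'
#' @param real,rand two [disease_pathway][search_pathway] objects.
#' @return a list with `shared_proteins` and `shared_interactions` counts.
#' @export
pathway_overlap <- function(real, rand) {
  stopifnot(inherits(real, "disease_pathway"),
            inherits(rand, "disease_pathway"))
  list(shared_proteins = length(intersect(real$proteins, rand$proteins)),
       shared_interactions = length(intersect(edge_keys(real$protein_edges),
                                              edge_keys(rand$protein_edges))))
}

#' Randomization experiment: pathways from rewired networks
#'
#' Runs the full pipeline — degree-preserving rewiring, largest connected
#' component, tree construction, pathway search — on `n_random` independent
#' randomizations of `net`, using the same disease proteins, and records for
#' each replicate the protein and interaction overlap with the real pathway
#' plus the four topological metrics of the replicate's pathway graph.
#' Replicate `r` uses seed `base_seed + r`, so each replicate is individually
#' reproducible. A replicate whose rewired largest component contains no
#' disease protein is recorded as failed, not fatal.
#'
#' If structure (rather than degree sequence alone) drives the real pathway,
#' only some of its proteins and interactions should reappear in pathways
#' from random networks.
#'
#' @param net the real network (connected; pass the LCC).
#' @param disease a [disease_gene_set][map_disease_genes] or character
#'   vector of disease protein identifiers.
#' @param n_random number of random networks (the reference design uses 100).
#' @param base_seed integer; replicate `r` is seeded with `base_seed + r`.
#' @param swaps_per_edge see [rewire_degree_preserving()].
#' @param neighborhood,stop_rule passed to [build_tree()] /
#'   [search_pathway()].
#' @param tree,pathway optionally, the precomputed real tree and pathway (to
#'   avoid recomputation); must correspond to `net` and `disease`.
#' @return an object of class `randomization_report`: a list with `real`
#'   (the real pathway, its protein/interaction counts and metrics),
#'   `replicates` (one data.frame row per replicate), and the experiment
#'   parameters.
#' @export
randomization_experiment <- function(net, disease, n_random = 100,
                                     base_seed = 1,
                                     swaps_per_edge = 10,
                                     neighborhood = c("inclusive",
                                                      "exclusive"),
                                     stop_rule = c("connected",
                                                   "single-module"),
                                     tree = NULL, pathway = NULL) {
  neighborhood <- match.arg(neighborhood)
  stop_rule <- match.arg(stop_rule)
  check_network(net)
  mapped <- disease_ids(disease)
  if (is.null(tree)) tree <- build_tree(net, neighborhood)
  if (is.null(pathway)) pathway <- search_pathway(tree, mapped, stop_rule)
  real_metrics <- compute_network_metrics(pathway)

  empty_row <- data.frame(replicate = integer(0), seed = numeric(0),
                          ok = logical(0), protein_overlap = integer(0),
                          interaction_overlap = integer(0),
                          pathway_level = integer(0),
                          n_pathway_proteins = integer(0),
                          n_vertices = integer(0), diameter = numeric(0),
                          characteristic_path_length = numeric(0),
                          clustering_coefficient = numeric(0),
                          fail_reason = character(0))
  rows <- vector("list", n_random)
  for (r in seq_len(n_random)) {
    seed_r <- base_seed + r
    row <- data.frame(replicate = r, seed = seed_r, ok = FALSE,
                      protein_overlap = NA_integer_,
                      interaction_overlap = NA_integer_,
                      pathway_level = NA_integer_,
                      n_pathway_proteins = NA_integer_,
                      n_vertices = NA_integer_, diameter = NA_real_,
                      characteristic_path_length = NA_real_,
                      clustering_coefficient = NA_real_,
                      fail_reason = NA_character_)
    res <- tryCatch({
      g_r <- rewire_degree_preserving(net, seed_r, swaps_per_edge)
      lcc_r <- largest_connected_component(g_r)
      mapped_r <- intersect(mapped, igraph::V(lcc_r)$name)
      if (length(mapped_r) == 0L)
        stop("no disease protein in the rewired largest component")
      tree_r <- build_tree(lcc_r, neighborhood)
      path_r <- search_pathway(tree_r, mapped_r, stop_rule)
      ov <- pathway_overlap(pathway, path_r)
      met <- compute_network_metrics(path_r)
      list(ov = ov, met = met, path = path_r)
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      row$ok <- TRUE
      row$protein_overlap <- res$ov$shared_proteins
      row$interaction_overlap <- res$ov$shared_interactions
      row$pathway_level <- res$path$level
      row$n_pathway_proteins <- length(res$path$proteins)
      row$n_vertices <- res$met$n_vertices
      row$diameter <- res$met$diameter
      row$characteristic_path_length <- res$met$characteristic_path_length
      row$clustering_coefficient <- res$met$clustering_coefficient
    } else {
      row$fail_reason <- conditionMessage(res)
    }
    rows[[r]] <- row
  }
  replicates <- if (n_random == 0L) empty_row
                else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(
    real = list(pathway = pathway,
                n_proteins = length(pathway$proteins),
                n_interactions = nrow(pathway$protein_edges),
                metrics = real_metrics),
    replicates = replicates,
    n_random = n_random, base_seed = base_seed,
    swaps_per_edge = swaps_per_edge,
    neighborhood = neighborhood, stop_rule = stop_rule
  ), class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  ok <- x$replicates$ok
  cat("Randomization experiment:", x$n_random, "degree-preserving rewired",
      "networks\n")
  cat("  real pathway: ", x$real$n_proteins, " proteins, ",
      x$real$n_interactions, " supporting interactions\n", sep = "")
  if (any(ok)) {
    po <- x$replicates$protein_overlap[ok]
    io <- x$replicates$interaction_overlap[ok]
    cat("  protein overlap with random pathways:     median ",
        stats::median(po), ", 95th pct ",
        stats::quantile(po, 0.95), "\n", sep = "")
    cat("  interaction overlap with random pathways: median ",
        stats::median(io), ", 95th pct ",
        stats::quantile(io, 0.95), "\n", sep = "")
  }
  if (any(!ok)) cat("  failed replicates: ", sum(!ok), "\n", sep = "")
  invisible(x)
}

#' Write a randomization report as TSV
#'
#' One row per replicate (overlap counts and the four metrics) followed by a
#' summary row labelled `real` carrying the real pathway's values.
#'
#' @param report a [randomization_report][randomization_experiment].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_randomization_report <- function(report, path) {
  stopifnot(inherits(report, "randomization_report"))
  df <- report$replicates
  df$fail_reason <- NULL
  real <- data.frame(replicate = "real", seed = NA, ok = TRUE,
                     protein_overlap = report$real$n_proteins,
                     interaction_overlap = report$real$n_interactions,
                     pathway_level = report$real$pathway$level,
                     n_pathway_proteins = report$real$n_proteins,
                     n_vertices = report$real$metrics$n_vertices,
                     diameter = report$real$metrics$diameter,
                     characteristic_path_length =
                       report$real$metrics$characteristic_path_length,
                     clustering_coefficient =
                       report$real$metrics$clustering_coefficient)
  df$replicate <- as.character(df$replicate)
  out <- rbind(df, real)
  tmp <- tempfile(tmpdir = dirname(path))
  write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
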