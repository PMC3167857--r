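#' Disease-risk modules at one hierarchy level
#'
#' A module is disease-risk if it contains at least one mapped disease
#' protein.
#'
#' @param h a `module_hierarchy` (one element of `tree$levels`).
#' @param disease a [disease_gene_set][map_disease_genes] or a character
#'   vector of mapped disease protein identifiers.
#' @return sorted integer vector of disease-risk module ids.
#' @export
mark_disease_risk_modules <- function(h, disease) {
  stopifnot(inherits(h, "module_hierarchy"))
  mapped <- disease_ids(disease)
  hit <- vapply(h$members, function(m) any(mapped %in% m), NA)
  sort(h$ids[hit])
}

#' Interactions among a set of disease-risk modules
#'
#' The subset of a level's module interactions with both endpoints in `risk`.
#'
#' @param h a `module_hierarchy`.
#' @param risk integer vector of module ids at this level.
#' @return integer edge matrix (two columns of module ids).
#' @export
risk_module_interactions <- function(h, risk) {
  stopifnot(inherits(h, "module_hierarchy"))
  risk <- as.integer(risk)
  if (!all(risk %in% h$ids))
    stop("unknown module id(s): ",
         paste(setdiff(risk, h$ids), collapse = ", "), call. = FALSE)
  e <- h$edges
  e[e[, 1L] %in% risk & e[, 2L] %in% risk, , drop = FALSE]
}

# Accept either a disease_gene_set or a plain character vector.
disease_ids <- function(disease) {
  ids <- if (inherits(disease, "disease_gene_set")) disease$mapped_ids
         else as.character(disease)
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L)
    stop("no mapped disease proteins", call. = FALSE)
  ids
}

# Is the graph (risk, edges) connected? Union-find on module ids.
risk_graph_connected <- function(risk, edges) {
  if (length(risk) <= 1L) return(TRUE)
  comp <- pair_components(length(risk),
                          matrix(match(edges, risk), ncol = 2L))
  length(unique(comp)) == 1L
}

#' Search the tree for the disease gene interaction pathway
#'
#' Walks the hierarchy bottom-up. At each level the disease-risk modules
#' (modules containing at least one mapped disease protein) and the
#' interactions among them are collected; the search stops at the *first*
#' level at which they are linked together, and returns that level's
#' risk-module graph as the disease gene interaction pathway. Because the
#' root level has a single module, the search always terminates.
#'
#' "Linked together" is interpreted as connectivity of the risk-module graph
#' (`stop_rule = "connected"`, the default): the weakest condition under
#' which every disease protein is reachable from every other through
#' disease-risk modules. The stricter reading — all disease proteins inside
#' one module — is available as `stop_rule = "single-module"`.
#'
#' @param tree a [module_tree][build_tree].
#' @param disease a [disease_gene_set][map_disease_genes] or character vector
#'   of disease protein identifiers present in the tree's network.
#' @param stop_rule `"connected"` (default) or `"single-module"`.
#' @return an object of class `disease_pathway`: a list with elements
#'   `level` (the stopping hierarchy), `risk_modules` (module ids),
#'   `pathway_edges` (module-id edge matrix), `disease_assignment` (named
#'   integer: disease protein -> containing module), `module_members` (named
#'   list id -> member identifiers), `proteins` (union of risk-module
#'   members), `protein_edges` (character matrix: the original-network
#'   interactions supporting the module interactions), and `stop_rule`.
#' @examples
#' g <- igraph::make_graph(c("A","B", "B","C", "C","D"), directed = FALSE)
#' tr <- build_tree(g)
#' p <- search_pathway(tr, c("A", "D"))
#' p$level            # 2: {A,C} and {B,D} interact
#' @export
search_pathway <- function(tree, disease,
                           stop_rule = c("connected", "single-module")) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(inherits(tree, "module_tree"))
  mapped <- disease_ids(disease)
  missing <- setdiff(mapped, tree$nodes)
  if (length(missing) > 0L)
    stop("disease protein(s) not in the clustered network: ",
         paste(missing, collapse = ", "), call. = FALSE)

  for (lv in seq_len(tree$n_levels)) {
    h <- tree$levels[[lv]]
    risk <- mark_disease_risk_modules(h, mapped)
    edges <- risk_module_interactions(h, risk)
    done <- if (stop_rule == "single-module") length(risk) == 1L
            else risk_graph_connected(risk, edges)
    if (done) {
      sel <- match(risk, h$ids)
      members <- h$members[sel]
      names(members) <- risk
      assignment <- vapply(mapped, function(p)
        risk[vapply(members, function(m) p %in% m, NA)], 0L)
      return(structure(list(
        level = lv,
        risk_modules = risk,
        pathway_edges = edges,
        disease_assignment = assignment,
        module_members = members,
        proteins = sort(unique(unlist(members, use.names = FALSE))),
        protein_edges = pathway_protein_edges(tree, lv, risk, edges),
        disease_proteins = sort(mapped),
        stop_rule = stop_rule,
        n_tree_levels = tree$n_levels
      ), class = "disease_pathway"))
    }
  }
  stop("internal error: root level should always satisfy the stop rule")
}

# Original-network edges supporting the pathway's module interactions: edges
# (u, v) whose endpoints lie in two different risk modules joined by a
# pathway edge.
pathway_protein_edges <- function(tree, level, risk, edges) {
  if (nrow(edges) == 0L)
    return(matrix(character(0), ncol = 2L))
  part <- level_partition(tree, level)
  el <- igraph::as_edgelist(tree$graph, names = TRUE)
  ma <- part[el[, 1L]]; mb <- part[el[, 2L]]
  ekeys <- paste(pmin(ma, mb), pmax(ma, mb))
  pkeys <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  sup <- el[ma != mb & ekeys %in% pkeys, , drop = FALSE]
  u <- pmin(sup[, 1L], sup[, 2L]); v <- pmax(sup[, 1L], sup[, 2L])
  o <- order(u, v)
  cbind(u[o], v[o])
}

#' @export
print.disease_pathway <- function(x, ...) {
  cat("Disease gene interaction pathway\n")
  cat("  found at hierarchy level ", x$level, " of ", x$n_tree_levels,
      " (stop rule: ", x$stop_rule, ")\n", sep = "")
  cat("  disease-risk modules:  ", length(x$risk_modules), "\n", sep = "")
  cat("  module interactions:   ", nrow(x$pathway_edges), "\n", sep = "")
  cat("  proteins covered:      ", length(x$proteins), " (",
      length(x$disease_proteins), " disease)\n", sep = "")
  invisible(x)
}

#' @export
summary.disease_pathway <- function(object, ...) {
  sizes <- lengths(object$module_members)
  ndis <- vapply(names(object$module_members), function(id)
    sum(object$disease_assignment == as.integer(id)), 0L)
  df <- data.frame(module_id = as.integer(names(object$module_members)),
                   n_members = as.integer(sizes),
                   n_disease = as.integer(ndis))
  df <- df[order(df$module_id), ]
  structure(list(level = object$level, modules = df,
                 n_edges = nrow(object$pathway_edges)),
            class = "summary.disease_pathway")
}

#' @export
print.summary.disease_pathway <- function(x, ...) {
  cat("Pathway at level", x$level, "with", nrow(x$modules), "modules and",
      x$n_edges, "module interactions\n")
  print(x$modules, row.names = FALSE)
  invisible(x)
}

#' @describeIn search_pathway plot the pathway's module graph; node area is
#'   proportional to the log module size, disease-hosting proteins counted in
#'   the label.
#' @param x a `disease_pathway`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.disease_pathway <- function(x, ...) {
  g <- pathway_module_graph(x)
  sizes <- lengths(x$module_members)[match(igraph::V(g)$name,
                                           names(x$module_members))]
  igraph::plot.igraph(
    g, vertex.size = 8 + 6 * log1p(sizes),
    vertex.color = adjustcolor("pink", 0.9),
    vertex.label = igraph::V(g)$name, ...)
  invisible(x)
}

# Module-level graph of a pathway (vertex names = module ids).
pathway_module_graph <- function(p) {
  stopifnot(inherits(p, "disease_pathway"))
  g <- igraph::graph_from_edgelist(
    matrix(as.character(p$pathway_edges), ncol = 2L), directed = FALSE)
  g + igraph::vertices(setdiff(as.character(p$risk_modules),
                               igraph::V(g)$name))
}

#' Export a disease pathway to disk
#'
#' `format = "json"` writes the full object (level, modules with members and
#' disease flags, module edges, supporting protein edges). `format = "sif"`
#' writes the module graph as `moduleID pp moduleID` lines for import into
#' network viewers. `format = "tsv"` writes one row per (module, member)
#' with a disease flag column.
#'
#' @param p a `disease_pathway`.
#' @param path output file.
#' @param format `"json"`, `"sif"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(p, path, format = c("json", "sif", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(p, "disease_pathway"))
  if (format == "json") {
    obj <- list(
      version = TREE_FORMAT_VERSION,
      level = p$level,
      stop_rule = p$stop_rule,
      risk_modules = p$risk_modules,
      pathway_edges = if (nrow(p$pathway_edges) > 0L)
        unname(p$pathway_edges) else matrix(integer(0), ncol = 2L),
      disease_assignment = as.list(p$disease_assignment),
      module_members = p$module_members,
      protein_edges = if (nrow(p$protein_edges) > 0L)
        unname(p$protein_edges) else matrix(character(0), ncol = 2L)
    )
    return(write_lines_atomic(
      jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path))
  }
  if (format == "sif") {
    lines <- if (nrow(p$pathway_edges) > 0L)
      paste(p$pathway_edges[, 1L], "pp", p$pathway_edges[, 2L])
    else paste(p$risk_modules)  # isolated module(s), no interactions
    return(write_lines_atomic(lines, path))
  }
  df <- do.call(rbind, lapply(names(p$module_members), function(id) {
    m <- p$module_members[[id]]
    data.frame(module_id = as.integer(id), member = m,
               is_disease = m %in% p$disease_proteins,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$module_id, df$member), ]
  tmp <- tempfile(tmpdir = dirname(path))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
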