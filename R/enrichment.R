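#' Read gene-set annotations in GMT format
#'
#' GMT is the standard tab-separated gene-set format: one set per line as
#' `term<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields are a parse error (a term must annotate at least one
#' protein). Duplicate term lines are merged by union with one warning.
#'
#' @param path path to a GMT file.
#' @return an object of class `annotation_catalog`: a list with `sets`
#'   (named list term -> unique member identifiers) and `descriptions`
#'   (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line ", line_no[bad[1L]], " in ", path,
         ": expected at least 3 tab-separated fields, got ", nf[bad[1L]],
         call. = FALSE)
  terms <- vapply(fields, `[`, "", 1L)
  descs <- vapply(fields, `[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (anyDuplicated(terms)) {
    warning("duplicate term(s) merged: ",
            paste(unique(terms[duplicated(terms)]), collapse = ", "),
            call. = FALSE)
    members <- lapply(split(members, terms), function(x)
      unique(unlist(x, use.names = FALSE)))
    descs <- descs[!duplicated(terms)]
    names(descs) <- terms[!duplicated(terms)]
    descs <- descs[names(members)]
  } else {
    names(members) <- terms
    names(descs) <- terms
  }
  structure(list(sets = members, descriptions = descs),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("Annotation catalog: ", length(x$sets), " term(s), ",
      length(unique(unlist(x$sets, use.names = FALSE))),
      " distinct proteins\n", sep = "")
  invisible(x)
}

#' Hypergeometric term enrichment of a module
#'
#' For each term annotating at least one module member, computes the exact
#' upper-tail hypergeometric probability of observing `k` or more annotated
#' members when drawing `n = |module|` proteins from a background of `N`
#' with `K` annotated — `P(X >= k)` with `X ~ Hypergeometric(N, K, n)` —
#' and flags significance at `threshold` (default 0.05, no multiple-testing
#' correction, matching the common raw-p workflow of annotation web tools;
#' set `adjust = "BH"` for Benjamini-Hochberg control, a deliberate
#' modernisation). Term membership is restricted to the background before
#' counting.
#'
#' The EASE-adjusted score used by some web tools is intentionally not
#' reproduced; this is the standard hypergeometric tail.
#'
#' @param members character vector: the module's member proteins. (A
#'   `module_id` element of a pathway's `module_members` works directly.)
#' @param catalog an [annotation_catalog][read_gmt].
#' @param background character vector of background proteins; conventionally
#'   all proteins of the analyzed network component. Every module member
#'   must be in the background.
#' @param threshold significance threshold in (0, 1), default 0.05.
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"` significance is
#'   assessed on the adjusted p-values.
#' @return a data.frame with columns `term`, `description`, `k`, `n`, `K`,
#'   `N`, `p_value` (and `p_adjusted` when `adjust = "BH"`), `significant`,
#'   sorted by p-value then term.
#' @examples
#' cat <- structure(list(sets = list(T1 = c("A", "B")),
#'                       descriptions = c(T1 = "demo")),
#'                  class = "annotation_catalog")
#' enrich_module(c("A", "B", "C"), cat, background = LETTERS[1:10])
#' # P(X >= 2) = choose(2,2)*choose(8,1)/choose(10,3) = 8/120
#' @export
enrich_module <- function(members, catalog, background, threshold = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(catalog, "annotation_catalog"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  members <- unique(as.character(members))
  background <- unique(as.character(background))
  outside <- setdiff(members, background)
  if (length(outside) > 0L)
    stop("module member(s) outside the background: ",
         paste(outside, collapse = ", "), call. = FALSE)
  N <- length(background)
  n <- length(members)
  k <- vapply(catalog$sets, function(s) length(intersect(s, members)), 0L)
  K <- vapply(catalog$sets, function(s) length(intersect(s, background)), 0L)
  sel <- k > 0L
  terms <- names(catalog$sets)[sel]
  k <- k[sel]; K <- K[sel]
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  df <- data.frame(term = terms,
                   description = unname(catalog$descriptions[terms]),
                   k = unname(k), n = n, K = unname(K), N = N,
                   p_value = unname(p), stringsAsFactors = FALSE)
  if (adjust == "BH") {
    df$p_adjusted <- p.adjust(df$p_value, method = "BH")
    df$significant <- df$p_adjusted < threshold
  } else {
    df$significant <- df$p_value < threshold
  }
  df[order(df$p_value, df$term), , drop = FALSE]
}

#' Enrichment of every module of a disease pathway
#'
#' Applies [enrich_module()] to each risk module of a pathway and binds the
#' results with a `module_id` column.
#'
#' @param pathway a [disease_pathway][search_pathway].
#' @param catalog an [annotation_catalog][read_gmt].
#' @param background background protein set; conventionally the node set of
#'   the clustered network component.
#' @param ... passed to [enrich_module()].
#' @return a data.frame (possibly 0-row) with `module_id` plus the
#'   [enrich_module()] columns.
#' @export
enrich_pathway <- function(pathway, catalog, background, ...) {
  stopifnot(inherits(pathway, "disease_pathway"))
  out <- lapply(names(pathway$module_members), function(id) {
    df <- enrich_module(pathway$module_members[[id]], catalog, background,
                        ...)
    if (nrow(df) > 0L) cbind(module_id = as.integer(id), df)
  })
  out <- out[!vapply(out, is.null, NA)]
  if (length(out) == 0L)
    return(data.frame(module_id = integer(0), term = character(0),
                      description = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_value = numeric(0), significant = logical(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Shared functions of interacting module pairs
#'
#' For each module interaction of a pathway, intersects the two modules'
#' *significant* term sets, and summarises the fraction of interactions
#' sharing at least one term — the module-level statement that interacting
#' disease-risk modules communicate through common biological functions.
#'
#' @param pathway a [disease_pathway][search_pathway].
#' @param enrichment a data.frame from [enrich_pathway()] (or an
#'   [enrich_module()] result bound with a `module_id` column) covering the
#'   pathway's modules; modules absent from it count as having no
#'   significant terms.
#' @return a list of class `shared_functions` with `edges` (data.frame:
#'   `module_a`, `module_b`, `n_shared_terms`, `shared_terms`
#'   (semicolon-collapsed)), `fraction_sharing` (interactions with >= 1
#'   shared term / total interactions; `NaN` when the pathway has no
#'   interactions), and `n_edges`.
#' @export
shared_functions <- function(pathway, enrichment) {
  stopifnot(inherits(pathway, "disease_pathway"),
            is.data.frame(enrichment))
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  terms_of <- function(id) sig$term[sig$module_id == id]
  e <- pathway$pathway_edges
  if (nrow(e) == 0L) {
    return(structure(list(
      edges = data.frame(module_a = integer(0), module_b = integer(0),
                         n_shared_terms = integer(0),
                         shared_terms = character(0)),
      fraction_sharing = NaN, n_edges = 0L), class = "shared_functions"))
  }
  shared <- lapply(seq_len(nrow(e)), function(r)
    sort(intersect(terms_of(e[r, 1L]), terms_of(e[r, 2L]))))
  edges <- data.frame(
    module_a = e[, 1L], module_b = e[, 2L],
    n_shared_terms = lengths(shared),
    shared_terms = vapply(shared, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  structure(list(edges = edges,
                 fraction_sharing = mean(edges$n_shared_terms > 0L),
                 n_edges = nrow(edges)),
            class = "shared_functions")
}

#' @export
print.shared_functions <- function(x, ...) {
  cat("Shared-function analysis of", x$n_edges, "module interaction(s)\n")
  if (x$n_edges > 0L)
    cat("  interactions sharing >= 1 significant term: ",
        sum(x$edges$n_shared_terms > 0L), " (",
        sprintf("%.1f%%", 100 * x$fraction_sharing), ")\n", sep = "")
  invisible(x)
}
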