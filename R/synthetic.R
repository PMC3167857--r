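#' Specification of a planted-module synthetic network
#'
#' Parameters of the stochastic-block-model-style generator used to test the
#' full module/pathway machinery without external data: a set of dense
#' planted modules sparsely wired to each other, with disease proteins
#' scattered over a few of them — the structural premise that disease genes
#' associate through associations between biological modules.
#'
#' Defaults describe the package's reference study condition: 5 modules of
#' 10 proteins, within-module edge probability 0.9, between-module 0.02,
#' 6 disease proteins spread over 3 planted modules.
#'
#' @param n_modules number of planted modules.
#' @param module_size_range integer `c(min, max)` module size (uniform).
#' @param p_within within-module edge probability; must exceed `p_between`.
#' @param p_between between-module edge probability.
#' @param n_disease number of disease proteins (>= 2, >= `disease_spread`).
#' @param disease_spread number of distinct planted modules hosting disease
#'   proteins.
#' @param seed integer seed making generation fully reproducible.
#' @return a validated list of class `planted_module_spec`.
#' @export
planted_module_spec <- function(n_modules = 5L,
                                module_size_range = c(10L, 10L),
                                p_within = 0.9, p_between = 0.02,
                                n_disease = 6L, disease_spread = 3L,
                                seed = 1L) {
  spec <- list(n_modules = as.integer(n_modules),
               module_size_range = as.integer(module_size_range),
               p_within = p_within, p_between = p_between,
               n_disease = as.integer(n_disease),
               disease_spread = as.integer(disease_spread),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_modules >= 1L, length(module_size_range) == 2L,
              module_size_range[1L] >= 2L,
              module_size_range[2L] >= module_size_range[1L])
    if (!(p_between >= 0 && p_between < p_within && p_within <= 1))
      stop("need 0 <= p_between < p_within <= 1", call. = FALSE)
    if (n_disease < 2L) stop("need n_disease >= 2", call. = FALSE)
    if (disease_spread < 1L || disease_spread > n_modules)
      stop("disease_spread must be in 1..n_modules", call. = FALSE)
    if (n_disease < disease_spread)
      stop("need n_disease >= disease_spread", call. = FALSE)
  })
  structure(spec, class = "planted_module_spec")
}

#' Generate a planted-module network with disease proteins
#'
#' Draws a stochastic-block-model-style graph from a
#' [planted_module_spec()]: within-module pairs are joined with probability
#' `p_within`, cross-module pairs with `p_between`. One deterministic
#' spanning edge is then added between each pair of consecutive planted
#' modules (first member to first member, chaining through module indices)
#' so that connectivity does not depend on rejection sampling. Disease
#' proteins are sampled from exactly `disease_spread` distinct planted
#' modules (each hosting at least one). Everything is reproducible from
#' `spec$seed`.
#'
#' @param spec a [planted_module_spec()].
#' @return a list with `network` (igraph), `assignment` (named integer:
#'   protein -> planted module), `disease` (a
#'   [disease_gene_set][map_disease_genes], fully mapped), and `spec`.
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "planted_module_spec"))
  with_seed(spec$seed, {
    sizes <- if (spec$module_size_range[1L] == spec$module_size_range[2L])
      rep.int(spec$module_size_range[1L], spec$n_modules)
    else sample(seq.int(spec$module_size_range[1L],
                        spec$module_size_range[2L]),
                spec$n_modules, replace = TRUE)
    n <- sum(sizes)
    nodes <- sprintf("P%04d", seq_len(n))
    assignment <- rep.int(seq_len(spec$n_modules), sizes)
    names(assignment) <- nodes

    pairs <- t(combn(n, 2L))
    same <- assignment[pairs[, 1L]] == assignment[pairs[, 2L]]
    p <- ifelse(same, spec$p_within, spec$p_between)
    keep <- runif(nrow(pairs)) < p
    el <- pairs[keep, , drop = FALSE]
    # deterministic spanning chain: first member of module i to first member
    # of module i + 1
    first <- match(seq_len(spec$n_modules), assignment)
    if (spec$n_modules > 1L)
      el <- rbind(el, cbind(first[-spec$n_modules], first[-1L]))
    g <- igraph::graph_from_edgelist(
      matrix(nodes[el], ncol = 2L), directed = FALSE)
    g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
    g <- igraph::simplify(g)
    g <- igraph::permute(g, match(igraph::V(g)$name, sort(nodes)))
    if (igraph::components(g)$no > 1L)
      stop("infeasible spec: generated network is disconnected even after ",
           "spanning-edge repair (raise p_within)", call. = FALSE)

    hosts <- sort(sample(spec$n_modules, spec$disease_spread))
    # one disease protein per hosting module first, remainder uniform over
    # the hosting modules' proteins
    pool <- nodes[assignment %in% hosts]
    picked <- vapply(hosts, function(h) sample(nodes[assignment == h], 1L),
                     "")
    extra <- spec$n_disease - length(picked)
    if (extra > 0L) {
      rest <- setdiff(pool, picked)
      if (length(rest) < extra)
        stop("infeasible spec: not enough proteins in the hosting modules ",
             "for n_disease", call. = FALSE)
      picked <- c(picked, sample(rest, extra))
    }
    disease <- sort(picked)
    list(network = g,
         assignment = assignment[sort(nodes)],
         disease = structure(list(raw_ids = disease, mapped_ids = disease,
                                  unmapped_ids = character(0)),
                             class = "disease_gene_set"),
         spec = spec)
  })
}

#' Generate annotations mirroring planted modules
#'
#' Builds an [annotation_catalog][read_gmt] with one "true" term per planted
#' module annotating its members — each member dropped independently with
#' probability `noise_rate` — plus `n_noise_terms` noise terms annotating
#' uniformly random protein subsets (sizes uniform on
#' `3..max(4, floor(n/4))`). True terms left empty by dropout are omitted
#' (a catalog term must annotate at least one protein).
#'
#' @param assignment named integer vector protein -> planted module, as
#'   returned by [generate_planted_network()].
#' @param n_noise_terms number of random noise terms.
#' @param noise_rate per-member dropout probability for true terms.
#' @param seed integer seed.
#' @return an `annotation_catalog`.
#' @export
generate_annotations <- function(assignment, n_noise_terms = 10L,
                                 noise_rate = 0.1, seed = 1L) {
  stopifnot(is.numeric(assignment), !is.null(names(assignment)),
            noise_rate >= 0, noise_rate <= 1, n_noise_terms >= 0L)
  nodes <- names(assignment)
  n <- length(nodes)
  with_seed(seed, {
    sets <- list(); descs <- character(0)
    for (m in sort(unique(assignment))) {
      memb <- nodes[assignment == m]
      memb <- memb[runif(length(memb)) >= noise_rate]
      if (length(memb) > 0L) {
        term <- sprintf("PLANTED_%02d", m)
        sets[[term]] <- sort(memb)
        descs[term] <- sprintf("true function of planted module %d", m)
      }
    }
    max_sz <- max(4L, n %/% 4L)
    for (i in seq_len(n_noise_terms)) {
      sz <- sample(3L:max_sz, 1L)
      term <- sprintf("NOISE_%02d", i)
      sets[[term]] <- sort(sample(nodes, min(sz, n)))
      descs[term] <- sprintf("random noise term %d", i)
    }
    structure(list(sets = sets, descriptions = descs),
              class = "annotation_catalog")
  })
}

#' Write an annotation catalog as GMT
#'
#' @param catalog an [annotation_catalog][read_gmt].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  lines <- vapply(names(catalog$sets), function(t)
    paste(c(t, catalog$descriptions[[t]], catalog$sets[[t]]),
          collapse = "\t"), "")
  write_lines_atomic(unname(lines), path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, ~0 for independent ones. Used to quantify how well
#' a tree level recovers the planted module assignment.
#'
#' @param a,b vectors of cluster labels over the same items (matched by
#'   names when both are named, else by position).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Best planted-module recovery across tree levels
#'
#' Scans every level of a tree and returns the maximal adjusted Rand index
#' of its partition against a reference assignment, with the level attaining
#' it.
#'
#' @param tree a [module_tree][build_tree].
#' @param assignment named vector protein -> reference cluster.
#' @return a list with `ari` and `level`.
#' @export
best_level_recovery <- function(tree, assignment) {
  stopifnot(inherits(tree, "module_tree"))
  ari <- vapply(seq_len(tree$n_levels), function(lv)
    adjusted_rand_index(level_partition(tree, lv), assignment), 0)
  list(ari = max(ari), level = which.max(ari))
}
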