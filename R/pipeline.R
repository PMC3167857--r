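#' Assemble and validate a pipeline configuration
#'
#' Builds the configuration driving [run_pipeline()]. Settings may come from
#' a YAML file, from arguments, or both; arguments win on conflict. Either
#' `edges` (+ `disease`) must point to existing input files, or
#' `simulate = TRUE` must request generation of synthetic inputs. Validation
#' happens here, before any computation.
#'
#' @param config_file optional path to a YAML file whose keys mirror the
#'   arguments below.
#' @param edges path to an edge-list file (TSV or SIF).
#' @param edge_format `"tsv"` or `"sif"`.
#' @param disease path to a disease gene-list file.
#' @param gmt optional path to a GMT annotation file (enables the
#'   enrichment stage).
#' @param out_dir output directory (created if needed).
#' @param simulate if `TRUE`, generate synthetic inputs from the default
#'   planted-module preset instead of reading `edges`/`disease`/`gmt`.
#' @param neighborhood,stop_rule,threshold,adjust,n_random,swaps_per_edge
#'   stage parameters, passed through to [build_tree()],
#'   [search_pathway()], [enrich_module()] and
#'   [randomization_experiment()].
#' @param seed integer master seed (simulation and randomization).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, edges = NULL,
                       edge_format = "tsv", disease = NULL, gmt = NULL,
                       out_dir = "modpath_out", simulate = FALSE,
                       neighborhood = "inclusive", stop_rule = "connected",
                       threshold = 0.05, adjust = "none", n_random = 0L,
                       swaps_per_edge = 10, seed = 1L) {
  cfg <- list(edges = edges, edge_format = edge_format, disease = disease,
              gmt = gmt, out_dir = out_dir, simulate = simulate,
              neighborhood = neighborhood, stop_rule = stop_rule,
              threshold = threshold, adjust = adjust,
              n_random = n_random, swaps_per_edge = swaps_per_edge,
              seed = seed)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file, call. = FALSE)
    from_file <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    # explicit arguments win over file values
    supplied <- names(match.call())[-1L]
    for (key in setdiff(names(from_file), supplied))
      cfg[[key]] <- from_file[[key]]
  }
  cfg$neighborhood <- match.arg(cfg$neighborhood,
                                c("inclusive", "exclusive"))
  cfg$stop_rule <- match.arg(cfg$stop_rule,
                             c("connected", "single-module"))
  cfg$adjust <- match.arg(cfg$adjust, c("none", "BH"))
  cfg$edge_format <- match.arg(cfg$edge_format, c("tsv", "sif"))
  stopifnot(is.numeric(cfg$threshold), cfg$threshold > 0,
            cfg$threshold < 1, cfg$n_random >= 0,
            cfg$swaps_per_edge > 0)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_random <- as.integer(cfg$n_random)
  if (!isTRUE(cfg$simulate)) {
    for (f in c("edges", "disease"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("input file for `", f, "` missing or not found",
             " (or set simulate: true)", call. = FALSE)
    if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
      stop("GMT file not found: ", cfg$gmt, call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) synthetic-data generation, network
#' loading and largest-connected-component extraction, disease gene
#' mapping, hierarchical tree construction, pathway search, (optional)
#' randomization experiment, and (optional) enrichment with
#' shared-function analysis. Every artifact is written atomically into
#' `cfg$out_dir`, and a `manifest.json` records inputs, parameters, seeds,
#' package version, per-stage timings and output files; on failure the
#' manifest is still written with the error and the stages completed.
#'
#' Outputs: `tree.json`, `pathway.json`, `pathway.sif`,
#' `pathway_modules.tsv`, plus `randomization.tsv` when `n_random > 0`,
#' `enrichment.tsv` and `shared_functions.tsv` when annotations are given,
#' and `sim_*` input files when `simulate = TRUE`.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory results (`tree`, `pathway`,
#'   and when computed `report`, `enrichment`, `shared`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "modpath",
                   version = as.character(packageVersion("modpath")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = unclass(cfg), stages = list(), outputs = list(),
                   status = "running")
  out <- function(name) file.path(cfg$out_dir, name)
  write_manifest <- function() {
    write_lines_atomic(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                        digits = NA, null = "null",
                                        pretty = TRUE),
                       out("manifest.json"))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  on.exit({
    if (identical(manifest$status, "running"))
      manifest$status <- "failed (partial outputs above)"
    write_manifest()
  })

  results <- list()
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      spec <- planted_module_spec(seed = cfg$seed)
      sim <- generate_planted_network(spec)
      write_edge_list(sim$network, out("sim_edges.tsv"))
      write_lines_atomic(sim$disease$mapped_ids, out("sim_disease.txt"))
      catalog <- generate_annotations(sim$assignment, seed = cfg$seed)
      write_gmt(catalog, out("sim_annotations.gmt"))
      truth <- data.frame(protein = names(sim$assignment),
                          planted_module = unname(sim$assignment))
      tmp <- tempfile(tmpdir = cfg$out_dir)
      write.table(truth, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
      file.rename(tmp, out("sim_truth.tsv"))
      sim
    })
    cfg$edges <- out("sim_edges.tsv")
    cfg$disease <- out("sim_disease.txt")
    cfg$gmt <- out("sim_annotations.gmt")
    cfg$edge_format <- "tsv"
    manifest$outputs$simulate <- c("sim_edges.tsv", "sim_disease.txt",
                                   "sim_annotations.gmt", "sim_truth.tsv")
  }

  net <- stage("load", {
    g <- read_edge_list(cfg$edges, cfg$edge_format)
    largest_connected_component(g)
  })
  disease <- stage("map_disease", map_disease_genes(cfg$disease, net))

  results$tree <- stage("build_tree", {
    tree <- build_tree(net, cfg$neighborhood)
    serialize_tree(tree, out("tree.json"))
    tree
  })
  manifest$outputs$tree <- "tree.json"

  results$pathway <- stage("find_pathway", {
    p <- search_pathway(results$tree, disease, cfg$stop_rule)
    write_pathway(p, out("pathway.json"), "json")
    write_pathway(p, out("pathway.sif"), "sif")
    write_pathway(p, out("pathway_modules.tsv"), "tsv")
    p
  })
  manifest$outputs$pathway <- c("pathway.json", "pathway.sif",
                                "pathway_modules.tsv")

  if (cfg$n_random > 0L) {
    results$report <- stage("randomize", {
      rep <- randomization_experiment(
        net, disease, n_random = cfg$n_random, base_seed = cfg$seed,
        swaps_per_edge = cfg$swaps_per_edge,
        neighborhood = cfg$neighborhood, stop_rule = cfg$stop_rule,
        tree = results$tree, pathway = results$pathway)
      write_randomization_report(rep, out("randomization.tsv"))
      rep
    })
    manifest$outputs$randomization <- "randomization.tsv"
  }

  if (!is.null(cfg$gmt)) {
    results$enrichment <- stage("enrich", {
      catalog <- read_gmt(cfg$gmt)
      enr <- enrich_pathway(results$pathway, catalog,
                            background = results$tree$nodes,
                            threshold = cfg$threshold, adjust = cfg$adjust)
      tmp <- tempfile(tmpdir = cfg$out_dir)
      write.table(enr, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
      file.rename(tmp, out("enrichment.tsv"))
      enr
    })
    results$shared <- stage("shared_functions", {
      sf <- shared_functions(results$pathway, results$enrichment)
      tmp <- tempfile(tmpdir = cfg$out_dir)
      write.table(sf$edges, tmp, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      file.rename(tmp, out("shared_functions.tsv"))
      sf
    })
    manifest$outputs$enrichment <- c("enrichment.tsv",
                                     "shared_functions.tsv")
  }

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()
  invisible(results)
}
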