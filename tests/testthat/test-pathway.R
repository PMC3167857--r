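test_that("disease-risk modules are exactly those containing disease proteins", {
  tr <- build_tree(path4())
  h1 <- tr$levels[[1]]
  expect_identical(mark_disease_risk_modules(h1, c("A", "C")),
                   h1$ids[match(c("A", "C"), unlist(h1$members))])
  h2 <- tr$levels[[2]]                  # modules {A,C} and {B,D}
  expect_identical(mark_disease_risk_modules(h2, c("A", "D")), h2$ids)
  expect_length(mark_disease_risk_modules(h2, c("A", "C")), 1)
  expect_error(mark_disease_risk_modules(h1, character(0)), "no mapped")
})

test_that("risk-module interactions are the induced edge subset", {
  tr <- build_tree(path4())
  h2 <- tr$levels[[2]]
  expect_identical(risk_module_interactions(h2, h2$ids), h2$edges)
  expect_equal(nrow(risk_module_interactions(h2, h2$ids[1])), 0)
  expect_error(risk_module_interactions(h2, 999L), "unknown module")
  h1 <- tr$levels[[1]]
  expect_identical(unname(risk_module_interactions(h1, h1$ids)),
                   unname(h1$edges))
})

test_that("pathway search stops at the first connected hierarchy", {
  tr <- build_tree(path4())
  p <- search_pathway(tr, c("A", "D"))
  expect_s3_class(p, "disease_pathway")
  expect_equal(p$level, 2)
  expect_length(p$risk_modules, 2)
  expect_equal(nrow(p$pathway_edges), 1)
  expect_setequal(p$proteins, c("A", "B", "C", "D"))
  expect_identical(sort(names(p$disease_assignment)), c("A", "D"))

  # adjacent disease proteins connect already at level 1
  p1 <- search_pathway(tr, c("A", "B"))
  expect_equal(p1$level, 1)
  expect_equal(nrow(p1$pathway_edges), 1)

  # disease proteins in one module: a single risk module, zero edges
  tri <- build_tree(g_from_pairs(c("A","B", "B","C", "C","A")))
  # A and C are adjacent so already connected at level 1 via their edge;
  # use the non-adjacent pair of the 4-path instead
  p2 <- search_pathway(tr, c("A", "C"))
  expect_equal(p2$level, 2)
  expect_length(p2$risk_modules, 1)
  expect_equal(nrow(p2$pathway_edges), 0)

  expect_error(search_pathway(tr, "Z"), "not in the clustered")
})

test_that("the single-module stop rule is stricter than connectivity", {
  tr <- build_tree(path4())
  p <- search_pathway(tr, c("A", "D"), stop_rule = "single-module")
  expect_equal(p$level, 3)              # only the root holds both
  expect_length(p$risk_modules, 1)
  pc <- search_pathway(tr, c("A", "C"), stop_rule = "single-module")
  expect_equal(pc$level, 2)
})

test_that("returned level is minimal, covers disease, risk count monotone", {
  for (seed in 1:15) {
    set.seed(seed)
    spread <- sample(2:3, 1)
    sim <- generate_planted_network(planted_module_spec(
      n_modules = 3L, module_size_range = c(5L, 7L), p_within = 0.8,
      p_between = 0.05, n_disease = sample(spread:5, 1),
      disease_spread = spread, seed = seed))
    tr <- build_tree(sim$network)
    d <- sim$disease$mapped_ids
    p <- search_pathway(tr, d)
    expect_true(all(d %in% p$proteins))
    risk_counts <- integer(tr$n_levels)
    for (lv in seq_len(tr$n_levels)) {
      h <- tr$levels[[lv]]
      risk <- mark_disease_risk_modules(h, d)
      risk_counts[lv] <- length(risk)
      edges <- risk_module_interactions(h, risk)
      comps <- brute_components(risk, edges)
      if (lv < p$level) expect_gt(length(comps), 1)
      if (lv == p$level) expect_equal(length(comps), 1)
    }
    expect_true(all(diff(risk_counts) <= 0))
  }
})

test_that("search agrees with the naive reference on all small graphs", {
  reps <- connected_graph_reps(5L)
  for (g in reps) {
    nodes <- sort(igraph::V(g)$name)
    if (length(nodes) < 3) next
    tr <- build_tree(g)
    naive <- naive_build_tree(g)
    subsets <- c(combn(nodes, 2, simplify = FALSE),
                 combn(nodes, 3, simplify = FALSE))
    for (d in subsets) {
      p <- search_pathway(tr, d)
      ref <- naive_search_pathway(naive, d)
      expect_equal(p$level, ref$level)
      expect_identical(p$risk_modules, ref$risk)
      expect_identical(unname(p$pathway_edges), unname(ref$edges))
    }
  }
})

test_that("protein-level edge support joins different interacting modules", {
  tr <- build_tree(path4())
  p <- search_pathway(tr, c("A", "D"))
  # pathway edge {A,C}-{B,D}: supporting protein edges are all three
  expect_identical(p$protein_edges,
                   cbind(c("A", "B", "C"), c("B", "C", "D")))
})

test_that("pathway exports are schema-valid and reload consistently", {
  tr <- build_tree(random_connected_graph(12, 0.25, 4))
  p <- search_pathway(tr, sort(igraph::V(tr$graph)$name)[c(1, 8)])
  fj <- withr::local_tempfile(fileext = ".json")
  write_pathway(p, fj, "json")
  pj <- jsonlite::fromJSON(fj, simplifyVector = FALSE)
  expect_equal(pj$level, p$level)
  expect_equal(as.integer(unlist(pj$risk_modules)), p$risk_modules)
  fs <- withr::local_tempfile(fileext = ".sif")
  write_pathway(p, fs, "sif")
  sif <- readLines(fs)
  expect_equal(length(sif), max(nrow(p$pathway_edges), 1))
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_pathway(p, ft, "tsv")
  tsv <- read.table(ft, header = TRUE, sep = "\t")
  expect_setequal(tsv$member, p$proteins)
  expect_setequal(tsv$member[tsv$is_disease], p$disease_proteins)
})
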