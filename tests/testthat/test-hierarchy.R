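test_that("Jaccard similarity hits its analytic anchors", {
  expect_equal(jaccard_similarity(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(jaccard_similarity(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard_similarity("B", c("B", "D")), 1 / 2)
  expect_equal(jaccard_similarity(character(0), character(0)), 0)
  expect_equal(jaccard_similarity(character(0), "A"), 0)
  expect_equal(jaccard_similarity(c("A", "A", "B"), c("B", "B", "A")), 1)
})

test_that("protein-level Jaccard agrees with igraph's vertex similarity", {
  g <- random_connected_graph(20, 0.2, seed = 7)
  ref <- igraph::similarity(g, method = "jaccard", loops = FALSE)
  nodes <- igraph::V(g)$name
  for (i in 1:19) for (j in (i + 1):20) {
    expect_equal(jaccard_similarity(module_neighborhood(nodes[i], g),
                                    module_neighborhood(nodes[j], g)),
                 ref[i, j])
  }
})

test_that("module neighborhoods follow the member-exclusion rule per mode", {
  g <- path4()
  expect_identical(module_neighborhood("B", g), c("A", "C"))
  expect_identical(module_neighborhood(c("A", "B"), g,
                                       mode = "exclusive"), "C")
  expect_identical(module_neighborhood(c("A", "B"), g),
                   c("A", "B", "C"))
  # star whose leaves are all inside the module: exclusive neighborhood empty
  star <- g_from_pairs(c("H","L1", "H","L2", "H","L3"))
  expect_identical(module_neighborhood(c("H", "L1", "L2", "L3"), star,
                                       mode = "exclusive"), character(0))
  expect_error(module_neighborhood("Z", g), "not in network")
})

test_that("merge_step merges exactly the maximally similar module pairs", {
  g <- path4()
  tr <- build_tree(g)
  h1 <- tr$levels[[1]]
  h2 <- merge_step(h1, tr$graph)
  # J(A,C) = J(B,D) = 1/2 is the exact maximum; both pairs merge
  expect_identical(h2$members, list(c("A", "C"), c("B", "D")))
  expect_identical(h2$ids, c(5L, 6L))
  expect_identical(unname(h2$edges), matrix(c(5L, 6L), 1))
  expect_identical(attr(h2, "s_star"), c(1, 2))

  # two twin leaves off a hub share an identical neighborhood: s* = 1,
  # everything else is carried forward unchanged
  twin <- g_from_pairs(c("H","T1", "H","T2", "H","X", "X","Y"))
  tt <- build_tree(twin)
  h2 <- tt$levels[[2]]
  merged <- h2$members[lengths(h2$members) > 1]
  expect_identical(merged, list(c("T1", "T2")))
  expect_identical(attr(h2, "s_star"), c(1, 1))
  carried <- h2$ids[lengths(h2$members) == 1]
  expect_true(all(carried %in% tt$levels[[1]]$ids))

  expect_error(merge_step(tt$levels[[tt$n_levels]], tt$graph),
               "single-module")
})

test_that("all-zero similarity collapses the level into the root", {
  # path of 4 at level 2 has two modules with disjoint neighborhoods
  tr <- build_tree(path4())
  expect_equal(tr$n_levels, 3)
  expect_identical(tr$levels[[3]]$members, list(c("A", "B", "C", "D")))
  expect_identical(attr(tr$levels[[3]], "s_star"), c(0, 1))
  expect_identical(sort(tr$levels[[3]]$children[[1]]), c(5L, 6L))
})

test_that("build_tree reproduces hand-derived small trees", {
  tr <- build_tree(path4())
  expect_equal(tr$n_levels, 3)
  expect_equal(vapply(tr$levels, function(h) length(h$ids), 0L),
               c(4L, 2L, 1L))

  # triangle: all three pairwise similarities equal 1/3, one tie component
  tri <- build_tree(g_from_pairs(c("A","B", "B","C", "C","A")))
  expect_equal(tri$n_levels, 2)
  expect_identical(tri$levels[[2]]$members, list(c("A", "B", "C")))
  expect_identical(attr(tri$levels[[2]], "s_star"), c(1, 3))

  # a single edge merges in one step
  e2 <- build_tree(g_from_pairs(c("A", "B")))
  expect_equal(e2$n_levels, 2)
})

test_that("degenerate networks are rejected with component counts", {
  expect_error(build_tree(g_from_pairs(c("A","B", "X","Y"))),
               "2 components")
  solo <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(solo)$name <- "A"
  expect_error(build_tree(solo), "at least 2")
})

test_that("two runs on the same network produce identical trees", {
  g <- random_connected_graph(25, 0.15, seed = 3)
  t1 <- build_tree(g)
  t2 <- build_tree(g)
  expect_identical(t1$levels, t2$levels)
  expect_identical(t1$nodes, t2$nodes)
})

test_that("tree invariants hold on random connected graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:40, 1)
    g <- random_connected_graph(n, 0.15, seed)
    tr <- build_tree(g)
    counts <- vapply(tr$levels, function(h) length(h$ids), 0L)
    expect_equal(counts[1], igraph::vcount(g))
    expect_equal(counts[tr$n_levels], 1L)
    expect_true(all(diff(counts) < 0))
    expect_lte(tr$n_levels, igraph::vcount(g))
    for (h in tr$levels) {
      members <- unlist(h$members)
      expect_identical(sort(members), tr$nodes)      # partition
      part <- setNames(rep.int(h$ids, lengths(h$members)), members)
      expect_identical(unname(tr$levels[[h$level]]$edges),
                       brute_module_edges(tr$graph, part))
    }
  }
})

test_that("optimized tree equals the naive reference on assorted graphs", {
  graphs <- list(path4(),
                 g_from_pairs(c("A","B", "B","C", "C","A", "C","D")),
                 random_connected_graph(10, 0.3, 1),
                 random_connected_graph(14, 0.2, 2))
  for (g in graphs) for (mode in c("inclusive", "exclusive")) {
    expect_tree_equals_naive(build_tree(g, mode),
                             naive_build_tree(g, mode))
  }
})

test_that("trees serialize to JSON and back losslessly", {
  tr <- build_tree(random_connected_graph(12, 0.25, 5))
  f <- withr::local_tempfile(fileext = ".json")
  serialize_tree(tr, f)
  tr2 <- deserialize_tree(f)
  strip <- function(levels) lapply(levels, function(h) {
    attr(h, "s_star") <- NULL
    h
  })
  expect_identical(strip(tr2$levels), strip(tr$levels))
  expect_identical(tr2$nodes, tr$nodes)
  expect_identical(tr2$neighborhood, tr$neighborhood)
  # the reconstructed graph carries the same edge set
  canon <- function(g) sort(apply(igraph::as_edgelist(g), 1, function(e)
    paste(sort(e), collapse = "|")))
  expect_identical(canon(tr2$graph), canon(tr$graph))
  # serialization is deterministic byte for byte
  f2 <- withr::local_tempfile(fileext = ".json")
  serialize_tree(tr2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("corrupt or tampered tree files are rejected on load", {
  expect_error(deserialize_tree(file.path(tempdir(), "absent.json")),
               "not found")
  f <- withr::local_tempfile()
  writeLines("{not json", f)
  expect_error(deserialize_tree(f), "corrupt")
  f2 <- withr::local_tempfile()
  writeLines('{"version": "9.9", "levels": []}', f2)
  expect_error(deserialize_tree(f2), "version")
  # tamper with a member list so that a protein appears in two modules
  tr <- build_tree(path4())
  f3 <- withr::local_tempfile()
  serialize_tree(tr, f3)
  txt <- readLines(f3)
  txt <- sub('"members":["A","C"]', '"members":["A","B"]', txt,
             fixed = TRUE)
  writeLines(txt, f3)
  expect_error(deserialize_tree(f3), "invalid tree")
})

test_that("flat membership export covers every level exactly once", {
  tr <- build_tree(random_connected_graph(8, 0.3, 9))
  df <- tree_membership(tr)
  expect_equal(nrow(df), length(tr$nodes) * tr$n_levels)
  for (lv in seq_len(tr$n_levels))
    expect_setequal(df$member[df$level == lv], tr$nodes)
  part <- level_partition(tr, 2)
  expect_named(part, tr$nodes)
  sub <- df[df$level == 2, ]
  expect_identical(unname(part[sub$member]), sub$module_id)
})
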