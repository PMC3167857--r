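make_catalog <- function(sets, descs = NULL) {
  if (is.null(descs)) descs <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descs),
            class = "annotation_catalog")
}

test_that("GMT files parse, merge duplicates, and reject short lines", {
  f <- withr::local_tempfile()
  writeLines(c("T1\tdesc one\tA\tB", "T2\tdesc two\tB\tC\tD"), f)
  cat <- read_gmt(f)
  expect_setequal(names(cat$sets), c("T1", "T2"))
  expect_identical(cat$sets$T1, c("A", "B"))
  expect_identical(cat$descriptions[["T2"]], "desc two")

  f2 <- withr::local_tempfile()
  writeLines(c("T1\td\tA", "T1\td\tB"), f2)
  expect_warning(cat2 <- read_gmt(f2), "duplicate")
  expect_identical(sort(cat2$sets$T1), c("A", "B"))

  f3 <- withr::local_tempfile()
  writeLines("T1\tdesc", f3)
  expect_error(read_gmt(f3), "line 1")
  f4 <- withr::local_tempfile()
  writeLines(character(0), f4)
  expect_error(read_gmt(f4), "empty")
})

test_that("hypergeometric tail reproduces the worked 8/120 value", {
  cat <- make_catalog(list(T1 = c("A", "B")))
  bg <- LETTERS[1:10]
  res <- enrich_module(c("A", "B", "C"), cat, bg)
  expect_equal(res$k, 2)
  expect_equal(res$K, 2)
  expect_equal(res$p_value, 8 / 120)
  expect_false(res$significant)         # 0.0667 > 0.05
})

test_that("terms covering the whole background give p = 1, never significant", {
  bg <- LETTERS[1:8]
  cat <- make_catalog(list(ALL = bg, NONE = c("Y", "Z")))
  res <- enrich_module(c("A", "B", "C"), cat, bg)
  expect_identical(res$term, "ALL")     # NONE has no module member: absent
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("module members outside the background are an error", {
  cat <- make_catalog(list(T1 = "A"))
  expect_error(enrich_module(c("A", "Q"), cat, LETTERS[1:5]),
               "outside the background")
})

test_that("tail probabilities equal exhaustive enumeration on small spaces", {
  bg <- sprintf("p%02d", 1:9)
  for (K in c(2, 4, 7)) for (n in c(1, 3, 5)) {
    cat <- make_catalog(list(TT = bg[seq_len(K)]))
    for (k in seq_len(min(n, K))) {
      if (n - k > 9 - K) next
      members <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
      res <- enrich_module(members, cat, bg)
      expect_equal(res$p_value, brute_hyper_tail(9, K, n, k))
    }
  }
})

test_that("p-value is monotone non-increasing in the overlap k", {
  bg <- sprintf("p%02d", 1:12)
  K <- 6
  cat <- make_catalog(list(TT = bg[seq_len(K)]))
  n <- 5
  p_prev <- Inf
  for (k in 1:5) {
    members <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
    res <- enrich_module(members, cat, bg)
    expect_lte(res$p_value, p_prev)
    p_prev <- res$p_value
  }
})

test_that("records are sorted by p then term and honour the BH option", {
  bg <- sprintf("p%02d", 1:20)
  cat <- make_catalog(list(STRONG = bg[1:4], WEAK = c(bg[1], bg[11:16]),
                           TIE_A = bg[1:3], TIE_B = bg[1:3]))
  res <- enrich_module(bg[1:4], cat, bg)
  expect_equal(res$term[1], "STRONG")
  expect_false(is.unsorted(res$p_value))
  ties <- res$term[res$p_value == res$p_value[2]]
  expect_identical(ties, sort(ties))
  res_bh <- enrich_module(bg[1:4], cat, bg, adjust = "BH")
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value))
  expect_identical(res_bh$significant, res_bh$p_adjusted < 0.05)
})

test_that("shared-function fractions count interacting enriched pairs", {
  tr <- build_tree(g_from_pairs(c("A","B", "B","C", "C","D", "D","E",
                                  "E","F", "F","A", "B","E")))
  p <- search_pathway(tr, c("A", "D"))
  enr <- data.frame(module_id = rep(p$risk_modules, each = 1),
                    term = "T1", significant = TRUE)
  sf <- shared_functions(p, enr)
  if (nrow(p$pathway_edges) > 0) {
    expect_equal(sf$fraction_sharing, 1)
    expect_true(all(sf$edges$n_shared_terms == 1))
  }
  # nothing significant: all counts zero
  enr0 <- enr; enr0$significant <- FALSE
  sf0 <- shared_functions(p, enr0)
  expect_true(all(sf0$edges$n_shared_terms == 0))
  if (nrow(p$pathway_edges) > 0) expect_equal(sf0$fraction_sharing, 0)
})

test_that("a two-edge pathway with one sharing edge yields fraction 1/2", {
  # all three proteins of a 3-path diseased: the level-1 pathway is the
  # two-edge chain of singleton risk modules
  g <- g_from_pairs(c("A","B", "B","C"))
  tr <- build_tree(g)
  p <- search_pathway(tr, c("A", "B", "C"))
  expect_equal(p$level, 1)
  expect_equal(nrow(p$pathway_edges), 2)
  e <- p$pathway_edges
  # annotate so that exactly one edge's endpoint modules share a term
  share_pair <- e[1, ]
  enr <- data.frame(module_id = c(share_pair, setdiff(p$risk_modules,
                                                      share_pair)),
                    term = c("S", "S",
                             sprintf("U%d", seq_along(
                               setdiff(p$risk_modules, share_pair)))),
                    significant = TRUE)
  sf <- shared_functions(p, enr)
  expect_equal(sum(sf$edges$n_shared_terms > 0), 1)
  expect_equal(sf$fraction_sharing, 1 / nrow(e))
})

test_that("enrichment on the planted preset flags the true module terms", {
  sim <- generate_planted_network(planted_module_spec(seed = 11L))
  catalog <- generate_annotations(sim$assignment, n_noise_terms = 5L,
                                  noise_rate = 0, seed = 11L)
  tr <- build_tree(sim$network)
  p <- search_pathway(tr, sim$disease)
  enr <- enrich_pathway(p, catalog, background = tr$nodes)
  expect_true(nrow(enr) > 0)
  sig <- enr[enr$significant, ]
  # the top significant hit of each risk module is a planted term
  top <- sig[!duplicated(sig$module_id), ]
  expect_true(all(grepl("^PLANTED_", top$term)))
})
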