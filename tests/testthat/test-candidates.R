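test_that("candidate dedup keeps the smallest-p occurrence with documented tie-breaks", {
  cnA <- forge_connectome("COREA", c("X", "Y"), p = c(0.002, 0.004))
  cnB <- forge_connectome("COREB", c("X", "Z"), p = c(0.005, 0.003))
  ex <- extract_candidates(list(cnA, cnB), alpha = 0.01,
                           core_set = c("COREA", "COREB"))
  expect_equal(ex$funnel[["occurrences"]], 4)
  expect_equal(ex$funnel[["deduplicated"]], 3)
  x <- ex$candidates[ex$candidates$candidate == "X", ]
  expect_equal(nrow(x), 1)
  expect_identical(x$closest_core, "COREA")
  expect_equal(x$p, 0.002)
  # ties on p: smaller distance wins, then lexicographic core
  cnC <- forge_connectome("COREC", "W", p = 0.002, distance = 5)
  cnD <- forge_connectome("CORED", "W", p = 0.002, distance = 4)
  ex2 <- extract_candidates(list(cnC, cnD), alpha = 0.01,
                            core_set = c("COREC", "CORED"))
  expect_identical(ex2$candidates$closest_core, "CORED")
  cnE <- forge_connectome("COREE", "W", p = 0.002, distance = 4)
  ex3 <- extract_candidates(list(cnE, cnD), alpha = 0.01,
                            core_set = c("COREE", "CORED"))
  expect_identical(ex3$candidates$closest_core, "CORED")
})

test_that("core genes are removed after occurrences are counted", {
  cn <- forge_connectome("COREA", c("COREB", "COREC"), p = c(0.001, 0.002))
  ex <- extract_candidates(list(cn), alpha = 0.01,
                           core_set = c("COREA", "COREB", "COREC"))
  expect_equal(ex$funnel[["occurrences"]], 2)
  expect_equal(ex$funnel[["deduplicated"]], 0)
  expect_equal(nrow(ex$candidates), 0)
})

test_that("extraction respects alpha as a strict threshold and validates it", {
  cn <- forge_connectome("COREA", c("X", "Y", "Z"), p = c(0.005, 0.01, 0.02))
  ex <- extract_candidates(list(cn), alpha = 0.01, core_set = "COREA")
  expect_identical(ex$candidates$candidate, "X")  # p = 0.01 is not < 0.01
  expect_error(extract_candidates(list(cn), alpha = 0, core_set = "COREA"),
               "alpha")
  expect_error(extract_candidates(list(cn), alpha = 1.2, core_set = "COREA"),
               "alpha")
})

test_that("funnel counts are monotone on real extractions", {
  w <- generate_world(n_genes = 150, n_modules = 3, p_within = 0.4,
                      p_between = 0.02, n_core = 10, n_holdout = 5, seed = 5)
  cns <- lapply(w$core, function(g) build_connectome(w$network, g))
  ex <- extract_candidates(cns, alpha = 0.05, core_set = w$core)
  expect_gte(ex$funnel[["occurrences"]], ex$funnel[["after_core_removal"]])
  expect_gte(ex$funnel[["after_core_removal"]], ex$funnel[["deduplicated"]])
  expect_false(any(ex$candidates$candidate %in% w$core))
  expect_false(anyDuplicated(ex$candidates$candidate) > 0)
})

test_that("hypergeometric enrichment matches exact combinatorics on a worked case", {
  # background of 20 genes, term annotates 5, core of 10 contains all 5
  bg <- sprintf("B%02d", 1:20)
  core <- bg[1:10]
  ann <- go_annotations(data.frame(gene = c(bg[1:5], bg),
                                   term = c(rep("T1", 5), rep("TALL", 20))))
  res <- go_enrichment(core, ann, background = bg, p_threshold = 1)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$p, 3003 / 184756, tolerance = 1e-12)
  expect_equal(t1$p, hyper_tail_oracle(5, 5, 20, 10), tolerance = 1e-12)
  expect_equal(t1$fold, (5 / 10) / (5 / 20))
  # a term annotating the whole background is never enriched
  expect_false("TALL" %in% res$term_id)  # p = 1 is not < 1
  all_res <- go_enrichment(core, ann, background = bg, p_threshold = 1,
                           method = "ease")
  expect_equal(attr(all_res, "n_terms_tested"), 2)
})

test_that("enrichment handles degenerate overlaps and validates the background", {
  bg <- sprintf("B%02d", 1:12)
  ann <- go_annotations(data.frame(gene = bg[7:9], term = "T1"))
  # k = 0: tail at zero is large, never selected at usual thresholds
  res <- go_enrichment(bg[1:4], ann, background = bg, p_threshold = 0.05)
  expect_equal(nrow(res), 0)
  expect_error(go_enrichment(c(bg[1], "GHOST"), ann, background = bg),
               "absent from background")
  # EASE is more conservative than the plain tail
  ann2 <- go_annotations(data.frame(gene = bg[1:4], term = "T2"))
  p_hyper <- go_enrichment(bg[1:6], ann2, background = bg, p_threshold = 1)$p
  p_ease <- go_enrichment(bg[1:6], ann2, background = bg, p_threshold = 1,
                          method = "ease")$p
  expect_gt(p_ease, p_hyper)
})

test_that("enrichment p-values are near-uniform when terms ignore modules", {
  gen <- generate_network(n_genes = 300, n_modules = 3, p_within = 0.05,
                          p_between = 0.05, seed = 17)
  ann <- generate_annotations(gen$module_of, n_terms = 250, affinity = 0.2,
                              background_rate = 0.2, seed = 18)
  set.seed(19)
  core <- sort(sample(names(gen$module_of), 30))
  res <- go_enrichment(core, ann, background = names(gen$module_of),
                       p_threshold = 1)
  # drop the catch-all (p exactly 1 by construction)
  p <- res$p[res$term_id != "T0000"]
  expect_gte(length(p), 200)
  # discrete conservative null: small p-values are not over-produced and the
  # bulk of the distribution sits mid-range
  expect_lte(mean(p < 0.05), 0.10)
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.75)
})

test_that("functional filtering keeps only candidates with enriched terms", {
  ann <- go_annotations(data.frame(gene = c("X", "Y"), term = c("T1", "T2")))
  df <- data.frame(candidate = c("X", "Y", "NOANN"),
                   closest_core = "C", distance = 1, rank = 1,
                   p = c(0.001, 0.002, 0.003), route = "r", degrees = 1L,
                   stringsAsFactors = FALSE)
  expect_message(out <- filter_candidates_by_function(df, "T1", ann), "removed")
  expect_identical(out$candidate, "X")
  expect_equal(attr(out, "removed"), 2)
  # with every term enriched, fully annotated candidates pass unchanged
  out2 <- filter_candidates_by_function(df[1:2, ], c("T1", "T2"), ann)
  expect_identical(out2$candidate, c("X", "Y"))
})

test_that("functional filtering concentrates candidates in disease modules", {
  frac_in <- function(genes, module_of, mods) mean(module_of[genes] %in% mods)
  before <- 0; after <- 0; n_before <- 0; n_after <- 0
  for (s in 1:10) {
    w <- generate_world(n_genes = 150, n_modules = 3, p_within = 0.4,
                        p_between = 0.04, n_core = 10, n_holdout = 3,
                        n_terms = 15, affinity = 0.9, background_rate = 0.05,
                        seed = 400 + s)
    cns <- lapply(w$core, function(g) build_connectome(w$network, g))
    ex <- extract_candidates(cns, alpha = 0.1, core_set = w$core)
    enr <- go_enrichment(w$core, w$annotations,
                         background = network_genes(w$network))
    filt <- suppressMessages(
      filter_candidates_by_function(ex, enr$term_id, w$annotations))
    before <- before + sum(w$module_of[ex$candidates$candidate] %in% 1)
    n_before <- n_before + nrow(ex$candidates)
    after <- after + sum(w$module_of[filt$candidate] %in% 1)
    n_after <- n_after + nrow(filt)
  }
  expect_gt(after / n_after, before / n_before)
})
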