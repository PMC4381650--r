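test_that("the generator is deterministic in parameters and seed", {
  w1 <- generate_world(n_genes = 120, n_modules = 3, p_within = 0.4,
                       p_between = 0.02, n_core = 10, n_holdout = 4,
                       n_terms = 12, seed = 7)
  w2 <- generate_world(n_genes = 120, n_modules = 3, p_within = 0.4,
                       p_between = 0.02, n_core = 10, n_holdout = 4,
                       n_terms = 12, seed = 7)
  expect_identical(direct_edges(w1$network), direct_edges(w2$network))
  expect_identical(w1$module_of, w2$module_of)
  expect_identical(w1$core, w2$core)
  expect_identical(w1$holdout, w2$holdout)
  expect_identical(as.data.frame(w1$annotations), as.data.frame(w2$annotations))
  # a different seed changes the edge set
  w3 <- generate_world(n_genes = 120, n_modules = 3, p_within = 0.4,
                       p_between = 0.02, n_core = 10, n_holdout = 4,
                       n_terms = 12, seed = 8)
  expect_false(identical(direct_edges(w1$network), direct_edges(w3$network)))
})

test_that("network generation honors its parameter contract", {
  gen <- generate_network(n_genes = 100, n_modules = 5, p_within = 0.3,
                          p_between = 0.01, conf_range = c(0.5, 0.999),
                          seed = 7)
  expect_length(gen$module_of, 100)
  expect_length(network_genes(gen$network), 100)
  ed <- direct_edges(gen$network)
  expect_true(all(ed$confidence >= 0.5 & ed$confidence <= 0.999))
  # symbols unique, upper-case, zero-padded for deterministic ordering
  expect_false(anyDuplicated(names(gen$module_of)) > 0)
  expect_true(all(grepl("^G\\d{4}$", names(gen$module_of))))
  # equal module sizes
  expect_true(all(table(gen$module_of) == 20))
  # parameter validation
  expect_error(generate_network(10, 2, p_within = 0.1, p_between = 0.5),
               "p_between <= p_within")
  expect_error(generate_network(10, 2, 0.5, 0.1, conf_range = c(0, 1)),
               "conf_range")
  expect_error(generate_network(2, 5, 0.5, 0.1), "n_genes >= n_modules")
})

test_that("extreme probabilities yield disjoint planted cliques", {
  gen <- generate_network(n_genes = 12, n_modules = 2, p_within = 1,
                          p_between = 0, seed = 9)
  ed <- direct_edges(gen$network)
  expect_equal(nrow(ed), 2 * choose(6, 2))
  same <- gen$module_of[ed$gene_a] == gen$module_of[ed$gene_b]
  expect_true(all(same))
  cross <- shortest_route(gen$network, names(gen$module_of)[1],
                          names(gen$module_of)[12])
  expect_false(cross$reachable)
})

test_that("within-module edge counts concentrate around expectation", {
  n <- 300; m <- 3; pw <- 0.3; pb <- 0.02
  gen <- generate_network(n, m, pw, pb, seed = 101)
  ed <- direct_edges(gen$network)
  same <- gen$module_of[ed$gene_a] == gen$module_of[ed$gene_b]
  pairs_within <- m * choose(n / m, 2)
  pairs_between <- choose(n, 2) - pairs_within
  mu_w <- pairs_within * pw
  sd_w <- sqrt(pairs_within * pw * (1 - pw))
  expect_lt(abs(sum(same) - mu_w), 5 * sd_w)
  mu_b <- pairs_between * pb
  sd_b <- sqrt(pairs_between * pb * (1 - pb))
  expect_lt(abs(sum(!same) - mu_b), 5 * sd_b)
})

test_that("core and holdout sets are disjoint, in-module, and size-checked", {
  gen <- generate_network(n_genes = 100, n_modules = 5, p_within = 0.3,
                          p_between = 0.01, seed = 7)
  sets <- plant_core_and_holdout(gen$module_of, disease_modules = c(1, 2),
                                 n_core = 20, n_holdout = 5, seed = 3)
  expect_length(sets$core, 20)
  expect_length(sets$holdout, 5)
  expect_length(intersect(sets$core, sets$holdout), 0)
  expect_true(all(gen$module_of[c(sets$core, sets$holdout)] %in% c(1, 2)))
  expect_error(plant_core_and_holdout(gen$module_of, 1, n_core = 18,
                                      n_holdout = 5, seed = 3),
               "need 23")
})

test_that("a planted core set is biologically tighter than random sets", {
  gen <- generate_network(n_genes = 150, n_modules = 3, p_within = 0.5,
                          p_between = 0.01, seed = 55)
  sets <- plant_core_and_holdout(gen$module_of, 1, n_core = 15, n_holdout = 0,
                                 seed = 56)
  obs <- median(pairwise_distances(gen$network, sets$core))
  set.seed(57)
  null_medians <- replicate(50, {
    median(pairwise_distances(gen$network,
                              sample(names(gen$module_of), 15)))
  })
  expect_lt(obs, median(null_medians))
})

test_that("annotations follow affinity extremes and guarantee coverage", {
  gen <- generate_network(n_genes = 60, n_modules = 3, p_within = 0.3,
                          p_between = 0.02, seed = 4)
  ann <- generate_annotations(gen$module_of, n_terms = 6, affinity = 1,
                              background_rate = 0, seed = 5)
  home <- attr(ann, "term_home")
  for (t in setdiff(names(ann$term2gene), "T0000")) {
    expect_setequal(ann$term2gene[[t]],
                    names(gen$module_of)[gen$module_of == home[[t]]])
  }
  # catch-all covers every gene, so each gene has at least one term
  expect_setequal(ann$term2gene[["T0000"]], names(gen$module_of))
  expect_true(all(lengths(ann$gene2term) >= 1))
  # same seed, same table
  ann2 <- generate_annotations(gen$module_of, n_terms = 6, affinity = 1,
                               background_rate = 0, seed = 5)
  expect_identical(as.data.frame(ann), as.data.frame(ann2))
  expect_error(generate_annotations(gen$module_of, 0, 0.5, 0.1), "n_terms")
  expect_error(generate_annotations(gen$module_of, 5, 1.5, 0.1), "affinity")
})

test_that("annotation maps are mutually consistent", {
  w <- generate_world(n_genes = 100, n_modules = 4, p_within = 0.4,
                      p_between = 0.02, n_core = 8, n_holdout = 3,
                      n_terms = 10, seed = 12)
  ann <- w$annotations
  for (g in sample(names(ann$gene2term), 10)) {
    for (t in ann$gene2term[[g]]) {
      expect_true(g %in% ann$term2gene[[t]])
    }
  }
  df <- as.data.frame(ann)
  expect_equal(nrow(df), sum(lengths(ann$gene2term)))
})

test_that("planted structure is detectable across seeds in the strong-separation regime", {
  # within/between probability ratio 30, well inside the >= 10 regime
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    gen <- generate_network(n_genes = 200, n_modules = 4, p_within = 0.3,
                            p_between = 0.01, seed = 1000 + s)
    sets <- plant_core_and_holdout(gen$module_of, 1, n_core = 15,
                                   n_holdout = 0, seed = 2000 + s)
    res <- median_clustering_test(gen$network, sets$core, n_sims = 99,
                                  seed = 3000 + s)
    if (res$p_empirical < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
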