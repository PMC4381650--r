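#!/usr/bin/env Rscript
# Stage 2: biological proximity of the core disease genes.
#
# Reads the simulated world, profiles the pairwise biological distances of
# the core set against the genome-wide distribution, and runs the
# median-distance permutation test (10,000 random same-size gene sets).

suppressPackageStartupMessages(library(geneconnectome))

edges <- read_edge_list("results/world/edges.tsv")
core <- read_gene_set("results/world/core.txt", "core")
net <- build_network(edges)

core_d <- pairwise_distances(net, core)
cat(sprintf("core set: %d genes, %d pairwise distances, median %.3f\n",
            length(core), length(core_d), median(core_d)))

# genome-wide background: distances among a large random gene sample
set.seed(7)
bg_genes <- sample(network_genes(net), 200)
bg_d <- pairwise_distances(net, bg_genes)
cat(sprintf("background sample: %d distances, median %.3f\n",
            length(bg_d), median(bg_d)))

profile <- rbind(core = bin_distances(core_d), background = bin_distances(bg_d))
print(round(profile, 3))

test <- median_clustering_test(net, core, n_sims = 10000, seed = 101)
print(test)

dir.create("results/clustering", recursive = TRUE, showWarnings = FALSE)
write.table(round(profile, 5), "results/clustering/distance_bins.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
jsonlite::write_json(
  list(observed_median = test$observed_median,
       background_median = median(bg_d),
       n_sims = test$n_sims, n_hits = test$n_hits,
       p_empirical = test$p_empirical, p_upper_bound = test$p_upper_bound),
  "results/clustering/permutation_test.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
cat("wrote results/clustering/\n")
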