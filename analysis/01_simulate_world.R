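#!/usr/bin/env Rscript
# Stage 1: simulate the reference study world.
#
# A 500-gene interactome with 5 planted modules (within-module edge
# probability 0.5 over a 0.005 background), STRING-like confidences in
# U(0.5, 0.999), one disease module supplying 25 "known" core genes and 10
# held-out validation genes, and 40 module-homed GO terms (affinity 0.9,
# background rate 0.05). All downstream stages read the files written here.

suppressPackageStartupMessages(library(geneconnectome))

seed <- 42L
world <- generate_world(seed = seed)
print(world)

dir.create("results", showWarnings = FALSE)
paths <- write_world(world, "results/world")
cat("wrote:\n")
cat(sprintf("  %s\n", paths))

ed <- direct_edges(world$network)
same <- world$module_of[ed$gene_a] == world$module_of[ed$gene_b]
cat(sprintf("edges: %d total, %d within-module, %d between-module\n",
            nrow(ed), sum(same), sum(!same)))
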