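#!/usr/bin/env Rscript
# Stage 5: functional genomic alignment.
#
# Builds the biological distance matrix over the core genes plus the
# filtered candidates and summarizes their joint structure with a
# neighbor-joining tree, written as Newick.

suppressPackageStartupMessages(library(geneconnectome))

core <- read_gene_set("results/world/core.txt", "core")
edges <- read_edge_list("results/world/edges.tsv")
net <- build_network(edges)
filt <- read.delim("results/candidates/candidates_filtered.tsv",
                   comment.char = "#", stringsAsFactors = FALSE)

leaves <- unique(c(core, filt$candidate))
cat(sprintf("tree over %d genes (%d core + %d candidates)\n",
            length(leaves), length(core), length(setdiff(leaves, core))))

D <- distance_matrix(net, leaves)
tree <- nj_tree(D)
cat(sprintf("neighbor-joining tree: %d leaves, %d negative branches clamped\n",
            length(tree$tip.label), attr(tree, "clamped")))

dir.create("results/fga", recursive = TRUE, showWarnings = FALSE)
to_newick(tree, file = "results/fga/fga_tree.nwk")
write.table(round(D, 4), "results/fga/distance_matrix.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("wrote results/fga/\n")
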