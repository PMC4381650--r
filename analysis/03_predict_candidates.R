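#!/usr/bin/env Rscript
# Stage 3: candidate prediction and functional filtering.
#
# Builds the connectome of every core gene, pools the top-5% entries (the
# desk-scale analogue of the genome-scale top-1% rule: at 500 genes each
# connectome contributes its 24 nearest genes, about a quarter of a planted
# module), removes core genes, deduplicates, and keeps only candidates
# carrying at least one GO term enriched among the core genes.

suppressPackageStartupMessages(library(geneconnectome))

edges <- read_edge_list("results/world/edges.tsv")
core <- read_gene_set("results/world/core.txt", "core")
ann <- read_annotations("results/world/annotations.tsv")
net <- build_network(edges)

alpha <- 0.05
go_p <- 0.05

cns <- lapply(intersect(core, network_genes(net)),
              function(g) build_connectome(net, g))
ex <- extract_candidates(cns, alpha = alpha, core_set = core)
print(ex)

background <- intersect(names(ann$gene2term), network_genes(net))
enr <- go_enrichment(intersect(core, background), ann,
                     background = background, p_threshold = go_p)
cat(sprintf("enriched GO terms (p < %g): %d of %d tested\n",
            go_p, nrow(enr), attr(enr, "n_terms_tested")))

filt <- filter_candidates_by_function(ex, enr$term_id, ann)
cat(sprintf("funnel: %d occurrences -> %d deduplicated -> %d after functional filter\n",
            ex$funnel[["occurrences"]], ex$funnel[["deduplicated"]], nrow(filt)))

dir.create("results/candidates", recursive = TRUE, showWarnings = FALSE)
meta <- list(alpha = alpha, go_p_threshold = go_p)
write_connectome(ex, "results/candidates/candidates.tsv", meta = meta)
write_connectome(enr, "results/candidates/enrichment.tsv", meta = meta)
write_connectome(filt, "results/candidates/candidates_filtered.tsv", meta = meta)
cat("wrote results/candidates/\n")
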