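Package: geneconnectome
Title: Disease-Gene Prioritization on a Weighted Gene Connectome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts novel disease-gene candidates from a core set of known
    disease genes using shortest-path biological distances on a weighted
    gene-interaction network. Provides the gene-connectome distance machinery
    (biological distances, shortest routes, degrees of separation), percentile
    ranking of genes by proximity to core genes, a permutation test for the
    biological clustering of a gene set, top-percentile candidate extraction
    with hypergeometric GO-term enrichment filtering, held-out validation, and
    functional-genomic-alignment phylogenies (neighbor joining on biological
    distance matrices). Includes a planted-module synthetic interactome
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
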