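#' Pipeline configuration
#'
#' Collects the paths, thresholds and seed for an end-to-end [run_pipeline()]
#' run. The single config seed derives per-stage seeds by fixed offsets
#' (clustering test: `seed + 101`; held-out validation: `seed + 202`), so
#' each stage is independently reproducible. All thresholds must lie in
#' (0, 1] and are echoed, with the seed, into every output's metadata header.
#'
#' @param edge_list path to the edge-list TSV.
#' @param core_set path to the core gene set file.
#' @param out_dir output directory.
#' @param annotations optional path to a gene-to-term annotation file; when
#'   absent the functional filter stage is skipped.
#' @param holdout_set optional path to a held-out validation gene set.
#' @param alpha top-percentile extraction threshold (default 0.01).
#' @param go_p_threshold GO enrichment selection threshold (default 0.05).
#' @param n_sims simulations for the permutation and validation tests
#'   (default 10000).
#' @param seed global integer seed (default 1).
#' @param weight_transform edge-weight transform name (default "reciprocal").
#' @param n_ref_policy connectome denominator policy (default "network").
#' @param max_tree_leaves cap on the functional-genomic-alignment tree size;
#'   when core + filtered candidates exceed it, the lowest-p candidates are
#'   kept (default 500).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(edge_list, core_set, out_dir,
                            annotations = NULL, holdout_set = NULL,
                            alpha = 0.01, go_p_threshold = 0.05,
                            n_sims = 10000L, seed = 1L,
                            weight_transform = "reciprocal",
                            n_ref_policy = "network",
                            max_tree_leaves = 500L) {
  for (nm in c("alpha", "go_p_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop("'", nm, "' must be a fraction in (0, 1]")
    }
  }
  if (n_sims < 1L) stop("'n_sims' must be >= 1")
  structure(list(edge_list = edge_list, core_set = core_set,
                 annotations = annotations, holdout_set = holdout_set,
                 out_dir = out_dir, alpha = alpha,
                 go_p_threshold = go_p_threshold,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 weight_transform = weight_transform,
                 n_ref_policy = n_ref_policy,
                 max_tree_leaves = as.integer(max_tree_leaves)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end candidate-gene pipeline
#'
#' Executes the full analysis: build the weighted network, compute the
#' connectome of every core gene, test the core set's biological clustering,
#' extract the top-percentile candidate pool with deduplication, filter
#' candidates by GO enrichment of the core set (when annotations are given),
#' test held-out enrichment (when a held-out set is given), and build the
#' neighbor-joining tree over core plus filtered candidates. Every
#' intermediate table is written under `config$out_dir` along with a
#' `manifest.json` recording the config echo and the funnel counts
#' (occurrences, after core removal, deduplicated, filtered). A `RUN.partial`
#' marker is present while the run is incomplete and removed on success; a
#' stage failure aborts with the stage name and cause.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(config$out_dir, "RUN.partial")
  writeLines("run in progress", partial)
  meta <- list(seed = config$seed, alpha = config$alpha,
               go_p_threshold = config$go_p_threshold,
               n_sims = config$n_sims,
               weight_transform = config$weight_transform,
               n_ref_policy = config$n_ref_policy)

  edges <- run_stage("read_inputs", read_edge_list(config$edge_list))
  core <- run_stage("read_inputs", read_gene_set(config$core_set, "core"))
  ann <- if (!is.null(config$annotations)) {
    run_stage("read_inputs", read_annotations(config$annotations))
  }
  holdout <- if (!is.null(config$holdout_set)) {
    run_stage("read_inputs", read_gene_set(config$holdout_set, "holdout"))
  }

  net <- run_stage("build_network",
                   build_network(edges, weight_transform = config$weight_transform))
  core_in <- intersect(core, net$genes)
  if (length(core_in) < length(core)) {
    message(length(core) - length(core_in),
            " core gene(s) absent from the network dropped")
  }

  connectomes <- run_stage("connectomes", {
    cns <- lapply(core_in, function(g)
      build_connectome(net, g, n_ref = config$n_ref_policy))
    names(cns) <- core_in
    dir.create(file.path(config$out_dir, "connectomes"), showWarnings = FALSE)
    for (cn in cns) {
      write_connectome(cn, file.path(config$out_dir, "connectomes",
                                     paste0(cn$core, ".tsv")), meta = meta)
    }
    cns
  })

  clustering <- run_stage("cluster_stats", {
    res <- median_clustering_test(net, core_in, n_sims = config$n_sims,
                                  seed = config$seed + 101L)
    jsonlite::write_json(
      list(observed_median = res$observed_median, n_sims = res$n_sims,
           n_hits = res$n_hits, p_empirical = res$p_empirical,
           p_upper_bound = res$p_upper_bound, seed = res$seed,
           set_size = res$set_size),
      file.path(config$out_dir, "clustering.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    res
  })

  extraction <- run_stage("predict", {
    ex <- extract_candidates(connectomes, alpha = config$alpha,
                             core_set = core)
    write_connectome(ex, file.path(config$out_dir, "candidates.tsv"),
                     meta = meta)
    ex
  })

  enrichment <- NULL
  filtered <- extraction$candidates
  if (!is.null(ann)) {
    enrichment <- run_stage("go_filter", {
      background <- intersect(names(ann$gene2term), net$genes)
      enr <- go_enrichment(intersect(core_in, background), ann,
                           background = background,
                           p_threshold = config$go_p_threshold)
      write_connectome(enr, file.path(config$out_dir, "enrichment.tsv"),
                       meta = meta)
      enr
    })
    filtered <- run_stage("go_filter",
                          filter_candidates_by_function(extraction,
                                                        enrichment$term_id,
                                                        ann))
  }
  write_connectome(filtered, file.path(config$out_dir, "candidates_filtered.tsv"),
                   meta = meta)

  validation <- NULL
  if (!is.null(holdout)) {
    validation <- run_stage("validate", {
      background <- setdiff(net$genes, core)
      res <- holdout_enrichment_test(filtered$candidate,
                                     intersect(holdout, background),
                                     background,
                                     n_sims = config$n_sims,
                                     seed = config$seed + 202L)
      jsonlite::write_json(
        list(N = res$N, K = res$K, n = res$n, k = res$k,
             p_exact = res$p_exact, p_empirical = res$p_empirical,
             p_upper_bound = res$p_upper_bound, n_sims = res$n_sims,
             seed = res$seed),
        file.path(config$out_dir, "holdout.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
      res
    })
  }

  tree <- run_stage("fga_tree", {
    leaves <- c(core_in, filtered$candidate)
    if (length(leaves) > config$max_tree_leaves) {
      n_cand <- config$max_tree_leaves - length(core_in)
      leaves <- c(core_in, head(filtered$candidate, max(n_cand, 0L)))
    }
    if (length(unique(leaves)) >= 3L) {
      D <- distance_matrix(net, leaves)
      tr <- nj_tree(D)
      to_newick(tr, file.path(config$out_dir, "fga_tree.nwk"))
      tr
    }
  })

  manifest <- list(
    package = "geneconnectome",
    version = as.character(utils::packageVersion("geneconnectome")),
    config = meta,
    n_genes = length(net$genes),
    n_edges = igraph::ecount(net$graph),
    n_core = length(core_in),
    funnel = c(as.list(extraction$funnel), list(filtered = nrow(filtered))),
    clustering = list(observed_median = clustering$observed_median,
                      n_hits = clustering$n_hits,
                      p_empirical = clustering$p_empirical),
    n_enriched_terms = if (!is.null(enrichment)) nrow(enrichment),
    holdout = if (!is.null(validation)) {
      list(k = validation$k, n = validation$n, p_exact = validation$p_exact,
           p_empirical = validation$p_empirical)
    })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  unlink(partial)
  invisible(list(network = net, connectomes = connectomes,
                 clustering = clustering, extraction = extraction,
                 enrichment = enrichment, filtered = filtered,
                 validation = validation, tree = tree, manifest = manifest))
}
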