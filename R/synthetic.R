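#' Generate a planted-module synthetic interactome
#'
#' Planted-partition (stochastic block model) generator: genes are split into
#' `n_modules` equal-size modules (remainder genes go to the last module) and
#' every unordered pair gains an edge with probability `p_within` when both
#' genes share a module, `p_between` otherwise. Edge confidences are drawn
#' uniformly from `conf_range`. Symbols are synthetic, unique, upper-case and
#' zero-padded (`G0001`, ...) so lexicographic tie-breaking is deterministic.
#' Identical parameters and seed yield an edge-for-edge identical network.
#'
#' @param n_genes number of genes (>= `n_modules`).
#' @param n_modules number of modules (>= 1).
#' @param p_within,p_between edge probabilities, `0 <= p_between <= p_within <= 1`.
#' @param conf_range length-2 numeric, confidence bounds within (0, 1].
#' @param seed integer seed.
#' @param weight_transform passed to [build_network()].
#' @return list with `network` (a `gene_network`) and `module_of` (named
#'   integer vector, gene -> module id).
#' @export
generate_network <- function(n_genes, n_modules, p_within, p_between,
                             conf_range = c(0.5, 0.999), seed = 1L,
                             weight_transform = "reciprocal") {
  if (n_modules < 1L || n_genes < n_modules) stop("need n_genes >= n_modules >= 1")
  if (!is.numeric(p_within) || !is.numeric(p_between) ||
      p_between < 0 || p_within > 1 || p_between > p_within) {
    stop("need 0 <= p_between <= p_within <= 1")
  }
  if (length(conf_range) != 2L || conf_range[1L] <= 0 || conf_range[2L] > 1 ||
      conf_range[1L] > conf_range[2L]) {
    stop("'conf_range' must be (low, high) within (0, 1] with low <= high")
  }
  width <- max(4L, nchar(as.character(n_genes)))
  symbols <- sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
  base <- n_genes %/% n_modules
  module_of <- setNames(pmin(((seq_len(n_genes) - 1L) %/% base) + 1L, n_modules),
                        symbols)

  i <- rep.int(seq_len(n_genes - 1L), times = (n_genes - 1L):1L)
  j <- unlist(lapply(seq_len(n_genes - 1L), function(k) (k + 1L):n_genes),
              use.names = FALSE)
  p_edge <- ifelse(module_of[i] == module_of[j], p_within, p_between)
  edges <- with_seed(seed, {
    keep <- runif(length(p_edge)) < p_edge
    data.frame(gene_a = symbols[i[keep]], gene_b = symbols[j[keep]],
               confidence = runif(sum(keep), conf_range[1L], conf_range[2L]),
               stringsAsFactors = FALSE)
  })
  net <- build_network(edges, weight_transform = weight_transform,
                       genes = symbols)
  list(network = net, module_of = module_of)
}

#' Plant core and held-out disease gene sets
#'
#' Samples the "known" (core) and held-out validation disease genes, disjoint
#' and without replacement, from the genes of the designated disease
#' module(s) only — the synthetic stand-in for an established disease gene
#' list plus recently discovered genes held back for validation.
#'
#' @param module_of named integer vector (gene -> module id) as returned by
#'   [generate_network()].
#' @param disease_modules integer vector of module ids regarded as disease
#'   modules.
#' @param n_core,n_holdout set sizes; their sum must not exceed the number of
#'   disease-module genes.
#' @param seed integer seed.
#' @return list with character vectors `core` and `holdout` (sorted).
#' @export
plant_core_and_holdout <- function(module_of, disease_modules, n_core,
                                   n_holdout, seed = 1L) {
  pool <- names(module_of)[module_of %in% disease_modules]
  if (length(pool) < n_core + n_holdout) {
    stop("disease modules hold ", length(pool), " genes; need ",
         n_core + n_holdout)
  }
  picked <- with_seed(seed, sample(pool, n_core + n_holdout))
  list(core = sort(picked[seq_len(n_core)]),
       holdout = sort(picked[n_core + seq_len(n_holdout)]))
}

#' Generate module-correlated GO annotations
#'
#' Each synthetic term is assigned a home module; a gene receives the term
#' with probability `affinity` when it belongs to the home module and
#' `background_rate` otherwise. A catch-all term (`T0000`) annotates every
#' gene, guaranteeing full coverage (it is never enriched in any proper gene
#' subset, since it annotates the whole background). Terms are flat labels —
#' no ontology DAG is emulated.
#'
#' @param module_of named integer vector (gene -> module id).
#' @param n_terms number of module-homed terms (>= 1).
#' @param affinity,background_rate annotation probabilities in \[0, 1\].
#' @param seed integer seed.
#' @return a `go_annotations` object; attribute `term_home` maps term id to
#'   its home module (NA for the catch-all).
#' @export
generate_annotations <- function(module_of, n_terms, affinity,
                                 background_rate, seed = 1L) {
  if (n_terms < 1L) stop("'n_terms' must be >= 1")
  if (affinity < 0 || affinity > 1 || background_rate < 0 || background_rate > 1) {
    stop("'affinity' and 'background_rate' must be in [0, 1]")
  }
  genes <- names(module_of)
  modules <- sort(unique(module_of))
  width <- max(4L, nchar(as.character(n_terms)))
  term_ids <- sprintf(paste0("T%0", width, "d"), seq_len(n_terms))
  res <- with_seed(seed, {
    home <- sample(modules, n_terms, replace = TRUE)
    rows <- lapply(seq_len(n_terms), function(t) {
      p <- ifelse(module_of == home[t], affinity, background_rate)
      hit <- runif(length(genes)) < p
      if (!any(hit)) return(NULL)
      data.frame(gene = genes[hit], term_id = term_ids[t],
                 stringsAsFactors = FALSE)
    })
    list(home = home, rows = rows)
  })
  catch_all <- data.frame(gene = genes, term_id = "T0000",
                          stringsAsFactors = FALSE)
  df <- do.call(rbind, c(res$rows[!vapply(res$rows, is.null, TRUE)],
                         list(catch_all)))
  term_names <- setNames(c("catch-all biological process",
                           sprintf("synthetic process of module %d", res$home)),
                         c("T0000", term_ids))
  ann <- go_annotations(df, term_names = term_names)
  attr(ann, "term_home") <- setNames(c(NA_integer_, res$home),
                                     c("T0000", term_ids))
  ann
}

#' Generate a complete synthetic world
#'
#' Composes the three generators with a single global seed, consumed in a
#' fixed documented order — edges (`seed`), gene sets (`seed + 1`),
#' annotations (`seed + 2`) — so each stage is independently reproducible.
#' The defaults are the package's reference study conditions: 500 genes in 5
#' equal modules, dense planted modules (`p_within = 0.5`) on a sparse
#' background (`p_between = 0.005`), confidences U(0.5, 0.999), one disease
#' module supplying 25 core and 10 held-out genes, and 40 module-homed terms
#' with strong within-module annotation affinity (0.9) over a 0.05 background
#' rate.
#'
#' @param n_genes,n_modules,p_within,p_between,conf_range see
#'   [generate_network()].
#' @param disease_modules,n_core,n_holdout see [plant_core_and_holdout()].
#' @param n_terms,affinity,background_rate see [generate_annotations()].
#' @param seed global integer seed.
#' @param weight_transform passed to [build_network()].
#' @return object of class `synthetic_world`: `network`, `module_of`, `core`,
#'   `holdout`, `annotations`, `params` (the generator arguments), `seed`.
#' @export
generate_world <- function(n_genes = 500L, n_modules = 5L, p_within = 0.5,
                           p_between = 0.005, conf_range = c(0.5, 0.999),
                           disease_modules = 1L, n_core = 25L, n_holdout = 10L,
                           n_terms = 40L, affinity = 0.9,
                           background_rate = 0.05, seed = 1L,
                           weight_transform = "reciprocal") {
  gen <- generate_network(n_genes, n_modules, p_within, p_between,
                          conf_range, seed = seed,
                          weight_transform = weight_transform)
  sets <- plant_core_and_holdout(gen$module_of, disease_modules, n_core,
                                 n_holdout, seed = seed + 1L)
  ann <- generate_annotations(gen$module_of, n_terms, affinity,
                              background_rate, seed = seed + 2L)
  params <- list(n_genes = n_genes, n_modules = n_modules,
                 p_within = p_within, p_between = p_between,
                 conf_range = conf_range, disease_modules = disease_modules,
                 n_core = n_core, n_holdout = n_holdout, n_terms = n_terms,
                 affinity = affinity, background_rate = background_rate,
                 seed = seed, weight_transform = weight_transform)
  structure(list(network = gen$network, module_of = gen$module_of,
                 core = sets$core, holdout = sets$holdout,
                 annotations = ann, params = params, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world (seed %d): %d genes in %d modules, %d edges\n",
              x$seed, length(x$module_of), x$params$n_modules,
              igraph::ecount(x$network$graph)))
  cat(sprintf("  core %d, holdout %d (disease module(s): %s); %d GO terms\n",
              length(x$core), length(x$holdout),
              paste(x$params$disease_modules, collapse = ","),
              length(x$annotations$term2gene)))
  invisible(x)
}
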