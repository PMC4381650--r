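#' GO annotation set
#'
#' A flat gene-to-term annotation table held as two mutually consistent maps:
#' gene -> term ids and term id -> annotated genes. Terms are flat labels (no
#' ontology DAG propagation is performed; annotations are taken as given).
#'
#' @param df data frame whose first two columns are gene symbol and term id.
#' @param term_names optional named character vector of human-readable term
#'   names (names are term ids).
#' @return object of class `go_annotations` with elements `gene2term`,
#'   `term2gene` (named lists of character vectors) and `term_name`.
#' @export
go_annotations <- function(df, term_names = NULL) {
  if (!is.data.frame(df) || ncol(df) < 2L) {
    stop("'df' must be a data frame with columns gene, term_id")
  }
  gene <- normalize_symbol(df[[1L]])
  term <- trimws(as.character(df[[2L]]))
  if (any(!nzchar(gene)) || any(!nzchar(term))) stop("empty gene or term id")
  key <- paste(gene, term)
  dup <- duplicated(key)
  gene <- gene[!dup]; term <- term[!dup]
  gene2term <- lapply(split(term, gene), function(v) sort(unique(v)))
  term2gene <- lapply(split(gene, term), function(v) sort(unique(v)))
  tn <- setNames(rep(NA_character_, length(term2gene)), names(term2gene))
  if (!is.null(term_names)) {
    common <- intersect(names(tn), names(term_names))
    tn[common] <- term_names[common]
  }
  structure(list(gene2term = gene2term, term2gene = term2gene, term_name = tn),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf("go_annotations: %d genes, %d terms, %d gene-term links\n",
              length(x$gene2term), length(x$term2gene),
              sum(lengths(x$gene2term))))
  invisible(x)
}

#' @export
as.data.frame.go_annotations <- function(x, ...) {
  data.frame(gene = rep(names(x$gene2term), lengths(x$gene2term)),
             term_id = unlist(x$gene2term, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Extract top-percentile candidate genes from core connectomes
#'
#' Pools, across the connectomes of all core genes, every entry with
#' percentile p-value below `alpha` (the "top alpha of the genome" rule; with
#' the default denominator policy this equals rank <= floor(alpha * n_ref)).
#' Occurrences are counted before any reduction, core genes are then removed,
#' and each remaining candidate is kept once — the occurrence with the
#' smallest p, ties broken by smaller distance, then lexicographic core
#' symbol. The surviving record names the candidate's closest core gene and
#' carries that connectome entry verbatim.
#'
#' @param connectomes list of `gene_connectome` objects (one per core gene).
#' @param alpha percentile threshold in (0, 1]; default 0.01 (top 1%).
#' @param core_set character vector of core gene symbols to exclude from the
#'   candidate list.
#' @return object of class `candidate_extraction`: `candidates` (data frame
#'   `candidate`, `closest_core`, `distance`, `rank`, `p`, `route`, `degrees`,
#'   sorted by (p, candidate)), `funnel` (named counts: `occurrences`,
#'   `after_core_removal`, `deduplicated`) and `alpha`.
#' @export
extract_candidates <- function(connectomes, alpha = 0.01, core_set) {
  if (!is.list(connectomes) || !all(vapply(connectomes, inherits, TRUE, "gene_connectome"))) {
    stop("'connectomes' must be a list of gene_connectome objects")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("'alpha' must be a fraction in (0, 1]")
  }
  core_set <- unique(normalize_symbol(core_set))
  pool <- lapply(connectomes, function(cn) {
    e <- cn$entries[cn$entries$p < alpha, , drop = FALSE]
    if (nrow(e)) e$closest_core <- cn$core
    e
  })
  pool <- do.call(rbind, pool[vapply(pool, nrow, 1L) > 0L])
  if (is.null(pool) || nrow(pool) == 0L) {
    pool <- data.frame(gene = character(0), distance = numeric(0),
                       rank = integer(0), p = numeric(0),
                       route = character(0), degrees = integer(0),
                       closest_core = character(0), stringsAsFactors = FALSE)
  }
  occurrences <- nrow(pool)
  pool <- pool[!pool$gene %in% core_set, , drop = FALSE]
  after_core <- nrow(pool)
  ord <- order(pool$p, pool$distance, pool$closest_core, pool$gene)
  pool <- pool[ord, , drop = FALSE]
  pool <- pool[!duplicated(pool$gene), , drop = FALSE]
  pool <- pool[order(pool$p, pool$gene), , drop = FALSE]
  out <- data.frame(candidate = pool$gene, closest_core = pool$closest_core,
                    distance = pool$distance, rank = pool$rank, p = pool$p,
                    route = pool$route, degrees = pool$degrees,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(candidates = out,
                 funnel = c(occurrences = occurrences,
                            after_core_removal = after_core,
                            deduplicated = nrow(out)),
                 alpha = alpha),
            class = "candidate_extraction")
}

#' @export
print.candidate_extraction <- function(x, ...) {
  cat(sprintf("candidate extraction (alpha = %g): %d occurrences -> %d after core removal -> %d candidates\n",
              x$alpha, x$funnel[["occurrences"]],
              x$funnel[["after_core_removal"]], x$funnel[["deduplicated"]]))
  invisible(x)
}

#' GO-term over-representation in a gene set
#'
#' One-tailed hypergeometric (Fisher) over-representation test: for each term
#' with `K` annotated genes among `N` background genes, the probability of
#' observing at least `k` annotated genes in a draw of `n` core genes is
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. Fold enrichment is
#' `(k/n) / (K/N)`. Terms with (raw, by default) p below `p_threshold` are
#' returned sorted by p.
#'
#' @param gene_set character vector of genes tested for enrichment (e.g. the
#'   core disease genes); must be contained in `background`.
#' @param annotations a `go_annotations` object.
#' @param background character vector of background genes (default: all
#'   annotated genes). Term annotations outside the background are ignored.
#' @param p_threshold selection threshold (default 0.05).
#' @param method `"hypergeometric"` (default) or `"ease"` (the EASE-style
#'   conservative variant that removes one overlapping gene before taking the
#'   tail, so single-gene overlaps are never significant).
#' @param adjust `"none"` (default, raw-p selection) or `"BH"`
#'   (Benjamini-Hochberg; selection is then on adjusted p).
#' @return data frame of selected terms: `term_id`, `name`, `k`, `n`, `K`,
#'   `N`, `fold`, `p` (and `p_adjust` when `adjust = "BH"`), sorted by
#'   ascending p; attribute `n_terms_tested` gives the number of terms
#'   examined.
#' @export
go_enrichment <- function(gene_set, annotations, background = NULL,
                          p_threshold = 0.05,
                          method = c("hypergeometric", "ease"),
                          adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(inherits(annotations, "go_annotations"))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("'p_threshold' must be in (0, 1]")
  }
  if (is.null(background)) background <- names(annotations$gene2term)
  bg <- sort(unique(normalize_symbol(background)))
  gs <- unique(normalize_symbol(gene_set))
  missing <- setdiff(gs, bg)
  if (length(missing)) {
    stop("gene(s) absent from background: ", paste(head(missing, 5L), collapse = ", "))
  }
  N <- length(bg)
  n <- length(gs)
  terms <- names(annotations$term2gene)
  res <- lapply(terms, function(t) {
    tg <- intersect(annotations$term2gene[[t]], bg)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, gs))
    p <- switch(method,
                hypergeometric = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
                ease = if (k <= 1L) 1 else phyper(k - 2L, K, N - K, n, lower.tail = FALSE))
    data.frame(term_id = t, name = unname(annotations$term_name[t]),
               k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(term_id = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  }
  n_tested <- nrow(res)
  if (adjust == "BH") {
    res$p_adjust <- p.adjust(res$p, method = "BH")
    sel <- res$p_adjust < p_threshold
  } else {
    sel <- res$p < p_threshold
  }
  res <- res[sel, , drop = FALSE]
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_terms_tested") <- n_tested
  res
}

#' Filter candidates by functional relevance
#'
#' Retains only candidates annotated with at least one enriched term — the
#' "similar biological function" filter applied after top-percentile
#' extraction. Input order is preserved; the removed count is reported in a
#' message and as an attribute. Unannotated candidates are removed.
#'
#' @param candidates a `candidate_extraction` object or its `candidates` data
#'   frame.
#' @param enriched_terms character vector of enriched term ids (e.g. the
#'   `term_id` column of [go_enrichment()]).
#' @param annotations a `go_annotations` object.
#' @return the filtered candidates data frame (attribute `removed` gives the
#'   number filtered out).
#' @export
filter_candidates_by_function <- function(candidates, enriched_terms, annotations) {
  stopifnot(inherits(annotations, "go_annotations"))
  df <- if (inherits(candidates, "candidate_extraction")) candidates$candidates else candidates
  if (!is.data.frame(df) || !"candidate" %in% names(df)) {
    stop("'candidates' must be a candidate_extraction or a data frame with a 'candidate' column")
  }
  enriched_terms <- unique(as.character(enriched_terms))
  keep <- vapply(df$candidate, function(g) {
    terms <- annotations$gene2term[[g]]
    !is.null(terms) && any(terms %in% enriched_terms)
  }, logical(1), USE.NAMES = FALSE)
  removed <- sum(!keep)
  if (removed > 0L) message(removed, " candidate(s) removed by the functional filter")
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
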