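#' Percentile p-value of a connectome rank
#'
#' The percentile p-value of the gene ranked `rank` among `n_ref` ranked genes
#' is simply `rank / n_ref`: the fraction of the genome at least as close to
#' the core gene. Reporting layers round to 5 decimals.
#'
#' @param rank 1-based integer rank(s).
#' @param n_ref connectome-size denominator (recycled against `rank`).
#' @return numeric vector of fractions in (0, 1].
#' @export
#' @examples
#' percentile_p(1, 14131)   # 7.08e-05, printed as 0.00007
percentile_p <- function(rank, n_ref) {
  if (!is.numeric(rank) || !is.numeric(n_ref)) stop("'rank' and 'n_ref' must be numeric")
  if (any(abs(rank - round(rank)) > 1e-8)) stop("'rank' must be integer-valued")
  if (any(n_ref < 1)) stop("'n_ref' must be >= 1")
  if (any(rank < 1 | rank > n_ref)) stop("'rank' must lie in 1..n_ref")
  rank / n_ref
}

#' Build a gene-specific connectome
#'
#' The connectome of a core gene is the list of all other genes ranked by
#' ascending biological distance to it, each with a 1-based rank and a
#' percentile p-value `rank / n_ref`. Ties in distance are broken by gene
#' symbol so ranks are reproducible.
#'
#' @param net a `gene_network`.
#' @param core gene symbol.
#' @param n_ref denominator policy for the percentile: `"network"` (default,
#'   the number of genes in the network — at genome scale this is the count of
#'   protein-coding genes with distance information), `"reachable"` (the
#'   number of ranked entries), or a positive number.
#' @return object of class `gene_connectome`: list with `core`, `entries`
#'   (data frame `gene`, `distance`, `rank`, `p`, `route`, `degrees`),
#'   `n_ref`, `n_ref_policy`.
#' @export
build_connectome <- function(net, core, n_ref = c("network", "reachable")) {
  sw <- single_source_distances(net, core)
  core <- attr(sw, "core")
  entries <- data.frame(gene = sw$target, distance = sw$distance,
                        stringsAsFactors = FALSE)
  ord <- order(entries$distance, entries$gene)
  entries <- entries[ord, , drop = FALSE]
  entries$rank <- seq_len(nrow(entries))
  if (is.numeric(n_ref)) {
    stopifnot(length(n_ref) == 1L, n_ref >= 1)
    nr <- n_ref
    policy <- "fixed"
  } else {
    policy <- match.arg(n_ref)
    nr <- switch(policy,
                 network = length(net$genes),
                 reachable = nrow(entries))
  }
  if (nrow(entries) == 0L) {
    warning("core gene '", core, "' is isolated: empty connectome")
    entries$p <- numeric(0)
  } else {
    entries$p <- percentile_p(entries$rank, nr)
  }
  entries$route <- sw$route[ord]
  entries$degrees <- sw$degrees[ord]
  rownames(entries) <- NULL
  structure(list(core = core, entries = entries, n_ref = nr,
                 n_ref_policy = policy),
            class = "gene_connectome")
}

#' @export
print.gene_connectome <- function(x, ...) {
  cat(sprintf("connectome of %s: %d ranked genes (n_ref = %d, policy '%s')\n",
              x$core, nrow(x$entries), x$n_ref, x$n_ref_policy))
  if (nrow(x$entries)) print(head(x$entries, 5L))
  invisible(x)
}

#' Distance-bin profile
#'
#' Bins biological distances into the five standard categories — small
#' (< 10), small-medium (10–20; 20 is the genome-wide median distance),
#' medium-large (20–30), large-very large (30–40) and very large (>= 40) —
#' and returns the proportion in each. Bins are half-open `[lo, hi)`: a value
#' on a boundary goes to the upper bin.
#'
#' @param distances numeric vector of finite, non-negative distances.
#' @return named numeric vector of 5 proportions (summing to 1 for non-empty
#'   input), with an integer `counts` attribute. Empty input yields an
#'   explicit empty profile of `NA` proportions with zero counts.
#' @export
bin_distances <- function(distances) {
  labels <- c("[0,10)", "[10,20)", "[20,30)", "[30,40)", "[40,Inf)")
  if (length(distances) == 0L) {
    out <- setNames(rep(NA_real_, 5L), labels)
    attr(out, "counts") <- setNames(integer(5L), labels)
    return(out)
  }
  if (any(!is.finite(distances))) stop("all distances must be finite")
  if (any(distances < 0)) stop("distances must be non-negative")
  idx <- findInterval(distances, c(0, 10, 20, 30, 40))
  counts <- tabulate(idx, nbins = 5L)
  out <- setNames(counts / length(distances), labels)
  attr(out, "counts") <- setNames(counts, labels)
  out
}

#' Pairwise biological distances within a gene set
#'
#' Computes the biological distance for every unordered pair of retained
#' genes. Genes absent from the network are dropped (a message reports how
#' many), as are unreachable pairs — missing distance information is never
#' replaced by a substituted large value.
#'
#' @param net a `gene_network`.
#' @param gene_set character vector of gene symbols.
#' @return numeric vector of finite pairwise distances; `C(m, 2)` values when
#'   all `m` retained genes are mutually reachable.
#' @export
pairwise_distances <- function(net, gene_set) {
  stopifnot(inherits(net, "gene_network"))
  gs <- unique(normalize_symbol(gene_set))
  keep <- gs %in% net$genes
  if (any(!keep)) {
    message(sum(!keep), " gene(s) absent from the network dropped")
  }
  gs <- gs[keep]
  if (length(gs) < 2L) return(numeric(0))
  D <- network_distances(net, v = gs, to = gs)
  vals <- D[upper.tri(D)]
  n_inf <- sum(!is.finite(vals))
  if (n_inf > 0L) message(n_inf, " unreachable pair(s) excluded")
  vals[is.finite(vals)]
}

#' Permutation test for the biological clustering of a gene set
#'
#' Tests whether a gene set is biologically closer-knit than chance: the
#' observed statistic is the median pairwise biological distance within the
#' set, and the null is built by drawing `n_sims` random gene sets of the
#' same retained size (without replacement) from the network and computing
#' their medians. The empirical p-value is the fraction of null sets with a
#' median strictly smaller than the observed one; when no null set beats the
#' observed median the result also carries the bound `< 1/n_sims`.
#'
#' @param net a `gene_network`, or a precomputed symmetric gene-by-gene
#'   distance matrix with symbol dimnames (useful when testing many sets on
#'   one network).
#' @param gene_set character vector of gene symbols (genes absent from the
#'   network are dropped with a message).
#' @param n_sims number of null sets (default 10000).
#' @param seed integer seed for the null draws.
#' @param exclude_set if `TRUE`, null sets are drawn from the network genes
#'   minus `gene_set`; default `FALSE` samples from all network genes.
#' @param pseudocount if `TRUE`, report the conservative
#'   `(n_hits + 1) / (n_sims + 1)` estimate instead of `n_hits / n_sims`.
#' @return object of class `permutation_test`: `observed_median`, `n_sims`,
#'   `n_hits`, `p_empirical`, `p_upper_bound` (`1/n_sims` when `n_hits == 0`,
#'   else `NA`), `seed`, `set_size`.
#' @export
median_clustering_test <- function(net, gene_set, n_sims = 10000L, seed = 1L,
                                   exclude_set = FALSE, pseudocount = FALSE) {
  if (inherits(net, "gene_network")) {
    D <- network_distances(net)
  } else if (is.matrix(net)) {
    D <- net
    if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
      stop("distance matrix must have matching row and column gene names")
    }
  } else {
    stop("'net' must be a gene_network or a named distance matrix")
  }
  if (n_sims < 1L) stop("'n_sims' must be >= 1")
  genes <- rownames(D)
  gs <- unique(normalize_symbol(gene_set))
  keep <- gs %in% genes
  if (any(!keep)) message(sum(!keep), " gene(s) absent from the network dropped")
  gs <- gs[keep]
  m <- length(gs)
  if (m < 2L) stop("gene set must retain at least 2 network genes")

  med_of <- function(idx) {
    sub <- D[idx, idx]
    v <- sub[upper.tri(sub)]
    median(v[is.finite(v)])
  }
  observed <- med_of(gs)

  pool <- if (exclude_set) setdiff(genes, gs) else genes
  if (m >= length(pool)) {
    warning("gene set spans the whole sampling pool; null medians are degenerate")
  }
  null_medians <- with_seed(seed, {
    vapply(seq_len(n_sims),
           function(i) med_of(sample(pool, m)),
           numeric(1))
  })
  n_hits <- sum(null_medians < observed)
  p <- if (pseudocount) (n_hits + 1) / (n_sims + 1) else n_hits / n_sims
  structure(list(observed_median = observed,
                 n_sims = as.integer(n_sims),
                 n_hits = as.integer(n_hits),
                 p_empirical = p,
                 p_upper_bound = if (n_hits == 0L) 1 / n_sims else NA_real_,
                 seed = as.integer(seed),
                 set_size = m),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("median-distance permutation test (set of %d genes)\n", x$set_size))
  cat(sprintf("  observed median: %.3f\n", x$observed_median))
  if (x$n_hits == 0L) {
    cat(sprintf("  0 of %d null medians smaller; p < %g\n",
                x$n_sims, x$p_upper_bound))
  } else {
    cat(sprintf("  %d of %d null medians smaller; p = %.4g\n",
                x$n_hits, x$n_sims, x$p_empirical))
  }
  invisible(x)
}
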