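#' Biological distance matrix for a gene list
#'
#' Builds the square, symmetric, zero-diagonal biological distance matrix
#' used as input to the functional-genomic-alignment tree. Genes absent from
#' the network are dropped with a message. If any pair is unreachable, genes
#' are removed greedily — at each step the gene with the most infinite
#' entries (ties broken lexicographically) — until the matrix is fully
#' finite; infinite distances are never imputed.
#'
#' @param net a `gene_network`.
#' @param genes character vector of gene symbols (>= 3 usable genes required).
#' @return numeric matrix with symbol dimnames; attribute `dropped` lists the
#'   genes removed for unreachability.
#' @export
distance_matrix <- function(net, genes) {
  stopifnot(inherits(net, "gene_network"))
  gs <- unique(normalize_symbol(genes))
  keep <- gs %in% net$genes
  if (any(!keep)) message(sum(!keep), " gene(s) absent from the network dropped")
  gs <- sort(gs[keep])
  if (length(gs) < 3L) stop("need at least 3 usable genes for a distance matrix")
  D <- network_distances(net, v = gs, to = gs)
  dropped <- character(0)
  while (any(!is.finite(D))) {
    inf_count <- rowSums(!is.finite(D))
    worst <- names(which(inf_count == max(inf_count)))
    victim <- min(worst)
    dropped <- c(dropped, victim)
    keep <- rownames(D) != victim
    D <- D[keep, keep, drop = FALSE]
    if (nrow(D) < 3L) stop("fewer than 3 mutually reachable genes remain")
  }
  if (length(dropped)) {
    message(length(dropped), " gene(s) dropped for unreachable pairs: ",
            paste(dropped, collapse = ", "))
  }
  attr(D, "dropped") <- dropped
  D
}

#' Neighbor-joining tree from a biological distance matrix
#'
#' The functional-genomic-alignment tree: a phylogeny algorithm applied to
#' biological distances instead of sequence divergences. Runs canonical
#' neighbor joining (via [ape::nj()]) on the matrix with labels pre-sorted
#' lexicographically, so the agglomeration scan order — and hence the tree —
#' is reproducible. Negative branch lengths (an artifact NJ permits on
#' non-additive input) are clamped to zero with the negative amount
#' transferred to the sibling branch, preserving leaf-to-leaf path lengths
#' through the parent node.
#'
#' @param D square symmetric numeric matrix with zero diagonal and label
#'   dimnames (or supply `labels`).
#' @param labels optional character vector of leaf labels (row order of `D`).
#' @return an unrooted `phylo` tree (ape); attribute `clamped` counts the
#'   negative branches adjusted.
#' @export
nj_tree <- function(D, labels = NULL) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    stop("'D' must be a square numeric matrix")
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(D)) stop("'labels' length must match the matrix")
    rownames(D) <- colnames(D) <- as.character(labels)
  }
  if (is.null(rownames(D))) stop("'D' must carry labels (dimnames or 'labels')")
  if (nrow(D) < 3L) stop("need at least 3 labels")
  if (max(abs(D - t(D))) > 1e-12) stop("'D' must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("'D' must have a zero diagonal")
  if (any(!is.finite(D))) stop("'D' must be finite (see distance_matrix for drops)")
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  tree <- ape::nj(D)
  clamped <- 0L
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[1L]
    deficit <- tree$edge.length[e]  # negative
    tree$edge.length[e] <- 0
    sibs <- setdiff(which(tree$edge[, 1L] == tree$edge[e, 1L]), e)
    if (length(sibs)) {
      tree$edge.length[sibs[1L]] <- tree$edge.length[sibs[1L]] + deficit
    }
    clamped <- clamped + 1L
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Serialize a tree to Newick
#'
#' Labels containing spaces or Newick metacharacters are single-quoted per
#' the Newick convention (internal quotes doubled).
#'
#' @param tree a `phylo` tree (e.g. from [nj_tree()]).
#' @param file optional output path; when given the Newick string is written
#'   there and returned invisibly.
#' @param digits significant digits for branch lengths (default 6).
#' @return the Newick string.
#' @export
to_newick <- function(tree, file = NULL, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  need <- grepl("[][ ():,;']", labs)
  if (any(need)) {
    # write.tree rewrites spaces even inside quotes, so emit placeholders and
    # splice the quoted originals back into the serialized string
    ph <- sprintf("xQUOTEPHx%dx", seq_along(labs))
    tree$tip.label[need] <- ph[need]
    txt <- ape::write.tree(tree, digits = digits)
    for (i in which(need)) {
      quoted <- paste0("'", gsub("'", "''", labs[i], fixed = TRUE), "'")
      txt <- sub(ph[i], quoted, txt, fixed = TRUE)
    }
  } else {
    txt <- ape::write.tree(tree, digits = digits)
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Enrichment of a held-out gene set among predicted candidates
#'
#' Quantifies the predictive power of a candidate list: given a background of
#' `N` genes of which `K` are candidates, and a held-out set of `n` genes
#' with `k` found among the candidates, reports the exact hypergeometric
#' upper tail `P(X >= k)` alongside an empirical estimate from `n_sims`
#' uniform random `n`-gene subsets of the background. The hit count of such a
#' subset is exactly hypergeometric, so simulations are drawn with
#' [stats::rhyper()]. When no simulation reaches `k` hits the result carries
#' the bound `< 1/n_sims`.
#'
#' @param candidate_set character vector of candidate genes (subset of
#'   `background`).
#' @param holdout_set character vector of held-out validation genes (subset
#'   of `background`).
#' @param background character vector of background genes (conventionally the
#'   network genes minus the core set).
#' @param n_sims number of random draws (default 10000).
#' @param seed integer seed for the simulations.
#' @return object of class `holdout_enrichment`: `N`, `K`, `n`, `k`,
#'   `p_exact`, `p_empirical`, `p_upper_bound`, `n_sims`, `seed`.
#' @export
holdout_enrichment_test <- function(candidate_set, holdout_set, background,
                                    n_sims = 10000L, seed = 1L) {
  bg <- unique(normalize_symbol(background))
  cand <- unique(normalize_symbol(candidate_set))
  hold <- unique(normalize_symbol(holdout_set))
  bad <- setdiff(hold, bg)
  if (length(bad)) stop("held-out gene(s) outside background: ",
                        paste(head(bad, 5L), collapse = ", "))
  bad <- setdiff(cand, bg)
  if (length(bad)) stop("candidate gene(s) outside background: ",
                        paste(head(bad, 5L), collapse = ", "))
  if (n_sims < 1L) stop("'n_sims' must be >= 1")
  N <- length(bg)
  K <- length(cand)
  n <- length(hold)
  k <- length(intersect(hold, cand))
  p_exact <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  sims <- with_seed(seed, rhyper(n_sims, K, N - K, n))
  hits <- sum(sims >= k)
  structure(list(N = N, K = K, n = n, k = k,
                 p_exact = p_exact,
                 p_empirical = hits / n_sims,
                 p_upper_bound = if (hits == 0L) 1 / n_sims else NA_real_,
                 n_sims = as.integer(n_sims),
                 seed = as.integer(seed)),
            class = "holdout_enrichment")
}

#' @export
print.holdout_enrichment <- function(x, ...) {
  cat(sprintf("held-out enrichment: %d of %d held-out genes among %d candidates (background %d)\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("  exact hypergeometric tail p = %.4g\n", x$p_exact))
  if (!is.na(x$p_upper_bound)) {
    cat(sprintf("  empirical (%d sims): 0 hits, p < %g\n", x$n_sims, x$p_upper_bound))
  } else {
    cat(sprintf("  empirical (%d sims): p = %.4g\n", x$n_sims, x$p_empirical))
  }
  invisible(x)
}
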