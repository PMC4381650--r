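#' Normalize a gene symbol
#'
#' Trims surrounding whitespace and upper-cases the symbol. No alias or
#' identifier mapping is attempted; symbols are taken at face value. The
#' operation is idempotent.
#'
#' @param x character vector of symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbol(c(" bcl10 ", "Card11"))
normalize_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Build a weighted gene network
#'
#' Constructs the undirected gene-interaction network on which all biological
#' distances are computed. Each edge carries an interaction confidence in
#' (0, 1] and a derived strictly positive weight; the biological distance
#' between two genes is the minimum total weight along any path. The default
#' `reciprocal` transform (weight = 1/confidence) makes a maximally confident
#' interaction (confidence 0.999) contribute a distance of 1.001, so direct
#' high-confidence neighbors sit at distance just above 1.
#'
#' Symbols are normalized with [normalize_symbol()]. Self-loop rows are
#' dropped with a warning; duplicate rows for the same unordered pair are
#' reduced to the maximum confidence (a message reports the count).
#'
#' @param edges data frame (or 3-column matrix) whose first three columns are
#'   gene A, gene B and interaction confidence in (0, 1].
#' @param weight_transform `"reciprocal"` (weight = 1/confidence, default) or
#'   `"neglog"` (weight = -log(confidence); requires confidence < 1 so that
#'   all weights stay strictly positive).
#' @param genes optional character vector of additional gene symbols to
#'   include as isolated vertices (genes with distance information but no
#'   retained interaction).
#' @return an object of class `gene_network` with elements `graph` (igraph),
#'   `genes` (sorted symbol vector) and `weight_transform`.
#' @export
#' @examples
#' net <- build_network(data.frame(a = "A", b = "B", conf = 0.5))
#' network_genes(net)
build_network <- function(edges, weight_transform = c("reciprocal", "neglog"),
                          genes = NULL) {
  weight_transform <- match.arg(weight_transform)
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 3) {
    stop("'edges' must be a data frame with at least 3 columns (gene_a, gene_b, confidence)")
  }
  ga <- normalize_symbol(edges[[1]])
  gb <- normalize_symbol(edges[[2]])
  conf <- suppressWarnings(as.numeric(edges[[3]]))
  if (any(!nzchar(ga)) || any(!nzchar(gb))) {
    bad <- which(!nzchar(ga) | !nzchar(gb))
    stop("empty gene symbol at row(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  bad <- which(!is.finite(conf) | conf <= 0 | conf > 1)
  if (length(bad)) {
    stop("confidence must be in (0, 1]; offending row(s): ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "")
  }
  loops <- ga == gb
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped")
    ga <- ga[!loops]; gb <- gb[!loops]; conf <- conf[!loops]
  }
  a <- pmin(ga, gb)
  b <- pmax(ga, gb)
  key <- paste(a, b, sep = "\t")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    message("reduced ", n_dup, " duplicate edge row(s); kept maximum confidence per pair")
  }
  # tapply over the pair key both deduplicates (max confidence) and yields a
  # deterministic lexicographic edge order
  conf_by_pair <- tapply(conf, key, max)
  keys <- names(conf_by_pair)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    a <- parts[, 1L]; b <- parts[, 2L]
  } else {
    a <- character(0); b <- character(0)
  }
  conf <- as.numeric(conf_by_pair)
  if (weight_transform == "neglog" && any(conf >= 1)) {
    stop("'neglog' transform requires confidence < 1 (zero-weight edges are not allowed)")
  }
  w <- switch(weight_transform,
              reciprocal = 1 / conf,
              neglog = -log(conf))
  all_genes <- sort(unique(c(a, b, normalize_symbol(genes %||% character(0)))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, confidence = conf, weight = w,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_genes, stringsAsFactors = FALSE))
  structure(list(graph = g, genes = all_genes,
                 weight_transform = weight_transform),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges (weights: %s)\n",
              length(x$genes), igraph::ecount(x$graph), x$weight_transform))
  invisible(x)
}

#' Genes of a network
#' @param net a `gene_network`.
#' @return sorted character vector of gene symbols.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$genes
}

check_gene <- function(net, gene, what = "gene") {
  gene <- normalize_symbol(gene)
  if (length(gene) != 1L || !gene %in% net$genes) {
    stop(what, " not in network: ", gene)
  }
  gene
}

# Weighted distance matrix (rows `v`, columns `to`); Inf marks unreachable
# pairs. Thin wrapper so every caller uses the same engine.
network_distances <- function(net, v = igraph::V(net$graph),
                              to = igraph::V(net$graph)) {
  D <- igraph::distances(net$graph, v = v, to = to,
                         weights = igraph::E(net$graph)$weight)
  # per-source runs can disagree in the last ulp; make symmetry exact by
  # keeping the smaller accumulation for each unordered pair
  if (nrow(D) == ncol(D) && identical(rownames(D), colnames(D))) {
    D[] <- pmin(D, t(D))
  }
  D
}

#' Biological distances and canonical routes from one core gene
#'
#' Runs a single-source shortest-path sweep from `core` and reconstructs, for
#' every reachable gene, the canonical shortest route and its degrees of
#' separation (number of edges on the route). Where several routes attain the
#' minimal distance, the canonical route has the fewest edges, and among those
#' the lexicographically smallest predecessor at every step — routes are
#' therefore reproducible across runs and platforms.
#'
#' @param net a `gene_network`.
#' @param core gene symbol present in the network.
#' @return data frame with one row per reachable gene (the core excluded):
#'   columns `target`, `distance`, `degrees`, `route` (gene symbols joined
#'   with `" <-> "`, core first). Rows are ordered by (distance, target).
#'   Attribute `core` carries the core symbol.
#' @export
single_source_distances <- function(net, core) {
  stopifnot(inherits(net, "gene_network"))
  core <- check_gene(net, core, "core gene")
  g <- net$graph
  d <- network_distances(net, v = core)[1L, ]
  nms <- names(d)

  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  if (nrow(el)) {
    nbr <- split(c(el[, 2L], el[, 1L]), c(el[, 1L], el[, 2L]))
    nbw <- split(c(w, w), c(el[, 1L], el[, 2L]))
  } else {
    nbr <- nbw <- list()
  }

  parent <- setNames(rep(NA_character_, length(d)), nms)
  hops <- setNames(rep(NA_integer_, length(d)), nms)
  hops[core] <- 0L

  # process genes in increasing distance (symbols break exact ties); every
  # predecessor on a shortest path has strictly smaller distance (weights > 0)
  # and is therefore already resolved
  ord <- order(d, nms)
  for (i in ord) {
    v <- nms[i]
    if (!is.finite(d[i])) break
    if (v == core) next
    us <- nbr[[v]]
    ws <- nbw[[v]]
    du <- d[us]
    ok <- which(is.finite(du) & abs(du + ws - d[i]) <= 1e-9 * max(1, d[i]))
    cand <- us[ok]
    h <- hops[cand]
    best <- cand[h == min(h)]
    parent[v] <- min(best)
    hops[v] <- min(h) + 1L
  }

  targets <- nms[is.finite(d) & nms != core]
  routes <- vapply(targets, function(t) {
    path <- t
    while (path[1L] != core) path <- c(parent[[path[1L]]], path)
    paste(path, collapse = " <-> ")
  }, character(1))
  out <- data.frame(target = targets,
                    distance = unname(d[targets]),
                    degrees = unname(hops[targets]),
                    route = unname(routes),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "core") <- core
  out
}

#' Shortest route between two genes
#'
#' @param net a `gene_network`.
#' @param source,target gene symbols present in the network.
#' @return a `route_result` list: `source`, `target`, `distance`, `route`
#'   (character vector of symbols including both endpoints), `degrees`
#'   (edge count on the route) and `reachable`. An unreachable target yields
#'   `reachable = FALSE`, `distance = Inf`, an empty route and `degrees = NA`
#'   — an explicit sentinel, never a substituted large distance.
#' @export
#' @examples
#' net <- build_network(data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"),
#'                                 conf = c(0.5, 1/3, 0.1)))
#' shortest_route(net, "A", "C")
shortest_route <- function(net, source, target) {
  stopifnot(inherits(net, "gene_network"))
  source <- check_gene(net, source, "source gene")
  target <- check_gene(net, target, "target gene")
  if (source == target) {
    return(structure(list(source = source, target = target, distance = 0,
                          route = source, degrees = 0L, reachable = TRUE),
                     class = "route_result"))
  }
  sw <- single_source_distances(net, source)
  row <- sw[sw$target == target, , drop = FALSE]
  if (nrow(row) == 0L) {
    return(structure(list(source = source, target = target, distance = Inf,
                          route = character(0), degrees = NA_integer_,
                          reachable = FALSE),
                     class = "route_result"))
  }
  structure(list(source = source, target = target,
                 distance = row$distance,
                 route = strsplit(row$route, " <-> ", fixed = TRUE)[[1L]],
                 degrees = as.integer(row$degrees), reachable = TRUE),
            class = "route_result")
}

#' @export
print.route_result <- function(x, ...) {
  if (x$reachable) {
    cat(sprintf("%s -> %s: distance %.3f, %d degree(s) of separation\n  %s\n",
                x$source, x$target, x$distance, x$degrees,
                paste(x$route, collapse = " <-> ")))
  } else {
    cat(sprintf("%s -> %s: unreachable\n", x$source, x$target))
  }
  invisible(x)
}

#' Direct edges of the network
#'
#' Returns the raw edge set (gene pairs at one degree of separation) with
#' confidences and weights — the input for any external layout or plotting
#' tool.
#'
#' @param net a `gene_network`.
#' @return data frame with columns `gene_a`, `gene_b` (lexicographically
#'   ordered within each row), `confidence`, `weight`, sorted by pair.
#' @export
direct_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  if (nrow(el) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      confidence = numeric(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(gene_a = pmin(el[, 1L], el[, 2L]),
                    gene_b = pmax(el[, 1L], el[, 2L]),
                    confidence = igraph::E(net$graph)$confidence,
                    weight = igraph::E(net$graph)$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
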