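# Independent oracles and fixture builders used across the suite. The
# shortest-path oracle enumerates all simple paths by depth-first search and
# is independent of the package's graph engine.

# edges: data frame gene_a, gene_b, weight (undirected). Returns the minimum
# total weight over all simple source->target paths and, among the minima,
# the smallest edge count.
brute_force_route <- function(edges, source, target) {
  nodes <- unique(c(edges$gene_a, edges$gene_b, source, target))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]; w <- edges$weight[r]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = w))
  }
  best <- list(distance = Inf, hops = NA_integer_)
  visit <- function(v, dist, hops) {
    if (v == target) {
      if (dist < best$distance - 1e-12 ||
          (abs(dist - best$distance) <= 1e-12 && hops < best$hops)) {
        best <<- list(distance = dist, hops = hops)
      }
      return(invisible())
    }
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      u <- nb$to[r]
      if (!u %in% names(on_path) || !on_path[[u]]) {
        on_path[[u]] <<- TRUE
        visit(u, dist + nb$w[r], hops + 1L)
        on_path[[u]] <<- FALSE
      }
    }
  }
  on_path <- setNames(as.list(rep(FALSE, length(nodes))), nodes)
  on_path[[source]] <- TRUE
  visit(source, 0, 0L)
  best
}

# all graphs on n labelled nodes: confidences assigned cyclically from
# `alphabet` over the selected edges of the complete graph
enumerate_weighted_graphs <- function(n, alphabet) {
  pairs <- t(combn(n, 2L))
  m <- nrow(pairs)
  syms <- sprintf("N%d", seq_len(n))
  lapply(0:(2^m - 1L), function(mask) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) > 0L)
    data.frame(gene_a = syms[pairs[sel, 1L]],
               gene_b = syms[pairs[sel, 2L]],
               confidence = alphabet[((sel - 1L) %% length(alphabet)) + 1L],
               stringsAsFactors = FALSE)
  })
}

# exact hypergeometric upper tail by direct combinatorial summation
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- max(k, 0L):min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# sum of edge weights along a " <-> " route string, NA if any hop is not an
# edge of the network
route_weight_sum <- function(net, route_str) {
  hops <- strsplit(route_str, " <-> ", fixed = TRUE)[[1L]]
  ed <- direct_edges(net)
  key <- paste(ed$gene_a, ed$gene_b)
  total <- 0
  for (i in seq_len(length(hops) - 1L)) {
    a <- min(hops[i], hops[i + 1L]); b <- max(hops[i], hops[i + 1L])
    j <- match(paste(a, b), key)
    if (is.na(j)) return(NA_real_)
    total <- total + ed$weight[j]
  }
  total
}

# small connected chain network with unit weights (confidence 1)
make_chain_network <- function(symbols) {
  n <- length(symbols)
  build_network(data.frame(gene_a = symbols[-n], gene_b = symbols[-1L],
                           confidence = 1, stringsAsFactors = FALSE))
}

# forge a connectome object with prescribed entries (for dedup-rule tests)
forge_connectome <- function(core, genes, p, distance = p, rank = seq_along(genes)) {
  entries <- data.frame(gene = genes, distance = distance,
                        rank = rank, p = p,
                        route = paste(core, genes, sep = " <-> "),
                        degrees = 1L, stringsAsFactors = FALSE)
  structure(list(core = core, entries = entries, n_ref = 1000L,
                 n_ref_policy = "fixed"),
            class = "gene_connectome")
}
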