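# Independent oracles used across the suite. These deliberately avoid the
# code paths (and, for betweenness, the library) they are checking.

# Hand step-up BH: sort ascending, p_(i) * m / i, cumulative min from the
# largest rank down, cap at 1, map back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_sum <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Upper-tail hypergeometric by literal enumeration of every size-n draw
# from a background of N items of which the first K are "in the pathway".
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Exhaustive shortest-path betweenness: enumerate all simple paths between
# every unordered pair by depth-first search on the adjacency matrix, keep
# the shortest, and credit interior vertices with the fraction of shortest
# paths through them. Normalized by (n-1)(n-2)/2.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  stopifnot(n >= 1, isTRUE(all(adj == t(adj))))
  bc <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- visited
        return(invisible(NULL))
      }
      for (w in which(adj[v, ] == 1)) {
        if (!(w %in% visited)) walk(w, c(visited, w))
      }
    }
    walk(s, s)
    paths
  }
  if (n >= 3) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0L) next
      len <- min(lengths(paths))
      shortest <- paths[lengths(paths) == len]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  bc / denom
}

# All labeled simple graphs on n nodes as adjacency matrices.
all_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    adj <- matrix(0L, n, n)
    for (e in which(bits == 1L)) {
      adj[pairs[1, e], pairs[2, e]] <- 1L
      adj[pairs[2, e], pairs[1, e]] <- 1L
    }
    adj
  })
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier) > 0L) {
    nxt <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Fixture paths
extdata <- function(f) system.file("extdata", f, package = "netpharm")

fixture_compounds <- function() read_compounds(extdata("antihistamine_properties.csv"))

fixture_enrichment <- function() {
  enrichment_table(utils::read.delim(extdata("covid_pathway_enrichment.tsv")))
}

fixture_ppi_centrality <- function() utils::read.delim(extdata("ppi_centrality.tsv"))
fixture_core_centrality <- function() utils::read.delim(extdata("ppi_core_centrality.tsv"))
fixture_docking <- function() parse_scores(extdata("grin2b_docking.tsv"))
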