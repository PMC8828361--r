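# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Local clustering by explicit triangle counting over an edge-list matrix.
brute_avg_clustering <- function(edges, n_nodes) {
  adj <- matrix(FALSE, n_nodes, n_nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[a, b] <- TRUE; adj[b, a] <- TRUE
  }
  lc <- vapply(seq_len(n_nodes), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    closed <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (adj[nb[i], nb[j]]) closed <- closed + 1
    }
    closed / (k * (k - 1) / 2)
  }, double(1))
  mean(lc)
}

# k-core by iterative peeling on an undirected edge list.
brute_kcore_nodes <- function(edges, n_nodes, k) {
  alive <- rep(TRUE, n_nodes)
  repeat {
    deg <- rep(0L, n_nodes)
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      if (alive[a] && alive[b]) {
        deg[a] <- deg[a] + 1L
        deg[b] <- deg[b] + 1L
      }
    }
    drop <- alive & deg < k
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  which(alive)
}

# Distinct out-neighbors per node from a directed edge list.
brute_out_degree <- function(edges_from, edges_to) {
  nodes <- sort(unique(c(edges_from, edges_to)))
  vapply(nodes, function(v) {
    length(unique(edges_to[edges_from == v]))
  }, integer(1)) |> stats::setNames(nodes)
}

# Co-share pair weights by per-user pair enumeration.
brute_coshare_weights <- function(user_domain, group_domains) {
  acc <- list()
  for (u in unique(user_domain$user_id)) {
    doms <- sort(unique(user_domain$domain[user_domain$user_id == u]))
    doms <- doms[doms %in% group_domains]
    if (length(doms) >= 2) {
      prs <- utils::combn(doms, 2)
      for (c_ in seq_len(ncol(prs))) {
        key <- paste(prs[1, c_], prs[2, c_], sep = "|")
        acc[[key]] <- (acc[[key]] %||% 0) + 1
      }
    }
  }
  unlist(acc)
}

# Random undirected graph as an edge matrix (indices), no self loops.
random_edges <- function(n_nodes, p) {
  prs <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(prs)) < p
  t(prs[, keep, drop = FALSE])
}

edges_to_igraph <- function(edges, n_nodes, directed = FALSE) {
  g <- igraph::make_empty_graph(n = n_nodes, directed = directed)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n_nodes))
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(edges)),
                           attr = list(weight = rep(1, nrow(edges))))
  }
  g
}
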