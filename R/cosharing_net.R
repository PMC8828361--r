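#' Build a domain co-sharing network for a source group
#'
#' For each user, forms the set of group domains they shared at least once;
#' every unordered pair within that set adds one to the pair's link weight,
#' so a link weight counts the distinct users who shared both endpoint
#' domains (share multiplicity is irrelevant). Every group domain is kept
#' as a node, isolated or not, so density statistics are comparable across
#' groups of equal cardinality.
#'
#' @param tweets tweet tibble.
#' @param group a [source_group()].
#' @return undirected weighted igraph whose vertex set is exactly
#'   `group$domains`, with graph attribute `group` set to the group name.
#' @export
build_coshare <- function(tweets, group) {
  stopifnot(inherits(group, "source_group"))
  if (length(group$domains) == 0) {
    abort("Source group is empty.", class = "misinfo_config_error")
  }
  n_url_tw <- lengths(tweets$urls)
  df <- tibble(
    user_id = rep(tweets$user_id, n_url_tw),
    domain = url_to_domain(unlist(tweets$urls, use.names = FALSE))
  ) |>
    filter(.data$domain %in% group$domains) |>
    distinct(.data$user_id, .data$domain)

  doms <- group$domains
  g <- igraph::make_empty_graph(n = length(doms), directed = FALSE)
  igraph::V(g)$name <- doms
  if (nrow(df) > 0) {
    inc <- Matrix::sparseMatrix(
      i = match(df$user_id, unique(df$user_id)),
      j = match(df$domain, doms),
      x = 1,
      dims = c(length(unique(df$user_id)), length(doms))
    )
    co <- Matrix::crossprod(inc)            # domain x domain co-share counts
    co <- Matrix::triu(co, k = 1)
    idx <- Matrix::which(co > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      w <- co[idx]
      g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]),
                             attr = list(weight = as.numeric(w)))
    }
  }
  igraph::set_graph_attr(g, "group", group$name)
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient on the binarized
#' (unweighted) graph; nodes with fewer than two neighbors contribute zero,
#' and an empty graph scores zero. High values in a co-sharing network
#' indicate a tightly grouped audience repeatedly sharing the same set of
#' sources.
#'
#' @param graph undirected igraph.
#' @return proportion in \[0, 1\].
#' @export
avg_clustering <- function(graph) {
  if (igraph::vcount(graph) == 0) return(0)
  lc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0
  mean(lc)
}

#' Average link weight over all possible node pairs
#'
#' Sum of edge weights divided by `n * (n - 1) / 2`, counting absent links
#' as zero. Averaging over possible pairs (rather than existing links) is
#' what makes a near-empty baseline network score near zero; an
#' existing-links-only variant is available via `existing_only`.
#'
#' @param graph undirected weighted igraph with at least 2 nodes.
#' @param existing_only divide by the number of existing links instead of
#'   all possible pairs.
#' @return mean link weight.
#' @export
avg_link_weight <- function(graph, existing_only = FALSE) {
  n <- igraph::vcount(graph)
  if (n < 2) {
    abort("Average link weight needs at least 2 nodes.",
          class = "misinfo_config_error")
  }
  w <- igraph::E(graph)$weight
  total <- if (length(w) == 0) 0 else sum(w)
  denom <- if (existing_only) max(igraph::ecount(graph), 1) else n * (n - 1) / 2
  total / denom
}

#' Density metrics of a co-sharing network relative to a baseline
#'
#' Computes average clustering coefficient and average link weight for a
#' target group network and a baseline (random-sources) network, and
#' reports the target/baseline ratios; the baseline's own relative values
#' are exactly 1. Ratios are invariant to domain relabeling.
#'
#' @param target co-sharing igraph for the group of interest.
#' @param baseline co-sharing igraph for the random baseline group.
#' @return tibble with one row per graph: `group`, `avg_clustering`,
#'   `avg_link_weight`, `rel_clustering`, `rel_link_weight`.
#' @export
relative_metrics <- function(target, baseline) {
  bc <- avg_clustering(baseline)
  bw <- avg_link_weight(baseline)
  if (bc <= 0 || bw <= 0) {
    abort(paste("Baseline network has zero density; draw a denser random",
                "sample or use more data."),
          class = "misinfo_config_error")
  }
  tc <- avg_clustering(target)
  tw <- avg_link_weight(target)
  tibble(
    group = c(igraph::graph_attr(target, "group") %||% "target",
              igraph::graph_attr(baseline, "group") %||% "random"),
    avg_clustering = c(tc, bc),
    avg_link_weight = c(tw, bw),
    rel_clustering = c(tc / bc, 1),
    rel_link_weight = c(tw / bw, 1)
  )
}
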