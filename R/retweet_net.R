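#' Build the weighted retweet network of misinformation-engaged users
#'
#' Restricts the stream to retweets whose retweeting user is flagged
#' `misinfo_engaged` (every retweet by a qualifying user is kept — the edge
#' itself need not carry a misinformation domain), and aggregates them into
#' a directed graph oriented retweeted -> retweeter, i.e. along information
#' flow, with edge weight the number of retweets between the ordered pair.
#' Self-retweets are dropped; the node set is exactly the users appearing as
#' an endpoint of at least one kept retweet.
#'
#' @param tweets tweet tibble.
#' @param profiles tibble from [build_profiles()] carrying
#'   `misinfo_engaged`.
#' @return directed weighted igraph with attributes `n_users` and `n_ties`
#'   recorded as graph attributes.
#' @export
build_retweet_graph <- function(tweets, profiles) {
  engaged <- profiles$user_id[profiles$misinfo_engaged]
  rts <- tweets |>
    filter(!is.na(.data$retweeted_user_id),
           .data$user_id %in% engaged,
           .data$retweeted_user_id != .data$user_id)
  edges <- rts |>
    count(from = .data$retweeted_user_id, to = .data$user_id,
          name = "weight")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  g <- igraph::set_graph_attr(g, "n_users", igraph::vcount(g))
  g <- igraph::set_graph_attr(g, "n_ties", nrow(edges))
  g
}

#' Rank users by out-degree prominence
#'
#' Out-degree here is the number of distinct users who retweeted the
#' account (unweighted out-neighbors under the information-flow
#' orientation), so the top of the ranking is the most widely retweeted
#' accounts. Ties are broken by user id.
#'
#' @param graph retweet graph from [build_retweet_graph()].
#' @param n number of users to return.
#' @return tibble with columns `user_id`, `out_degree`.
#' @export
prominent_users <- function(graph, n) {
  if (n < 1) abort("`n` must be at least 1.", class = "misinfo_config_error")
  deg <- igraph::degree(graph, mode = "out")
  out <- tibble(user_id = names(deg), out_degree = as.integer(deg)) |>
    arrange(desc(.data$out_degree), .data$user_id)
  head(out, n)
}

#' Prune bot-like accounts from a retweet graph
#'
#' Removes nodes that tweet frequently but are never retweeted: original
#' tweet count at least `rate_threshold` and zero out-degree (no retweeters,
#' under the information-flow orientation). The rule is conjunctive — a
#' heavy tweeter with even one retweeter stays.
#'
#' @param graph retweet graph.
#' @param tweet_counts named integer vector of per-user original tweet
#'   counts (see [original_tweet_counts()]).
#' @param rate_threshold removal threshold on the tweet count; the pipeline
#'   default is the 95th percentile of per-user counts.
#' @return list with `graph` (the pruned graph) and `removed` (character
#'   vector of removed user ids).
#' @export
prune_bots <- function(graph, tweet_counts, rate_threshold) {
  nodes <- igraph::V(graph)$name
  cnt <- tweet_counts[nodes]
  cnt[is.na(cnt)] <- 0
  outdeg <- igraph::degree(graph, mode = "out")
  removed <- nodes[cnt >= rate_threshold & outdeg == 0]
  list(graph = igraph::delete_vertices(graph, removed),
       removed = sort(removed))
}

#' Per-user original tweet counts
#'
#' @param tweets tweet tibble.
#' @return named integer vector (user id -> count of original tweets).
#' @export
original_tweet_counts <- function(tweets) {
  orig <- tweets[is.na(tweets$retweeted_user_id), ]
  tab <- table(orig$user_id)
  setNames(as.integer(tab), names(tab))
}

#' k-core of a graph
#'
#' Maximal induced subgraph in which every node has at least `k` neighbors
#' within the subgraph. Degree is counted on the undirected simplification
#' (each neighbor once, regardless of edge direction or weight), the
#' standard k-core; the 100-core was used to isolate the elite accounts of
#' the retweet network. The result may be empty.
#'
#' @param graph igraph (directed graphs are collapsed to undirected for the
#'   degree computation; the returned subgraph keeps the input's edges).
#' @param k minimum within-subgraph degree.
#' @return induced subgraph of `graph`.
#' @export
k_core <- function(graph, k) {
  if (k < 1) abort("`k` must be at least 1.", class = "misinfo_config_error")
  und <- igraph::as_undirected(graph, mode = "collapse")
  core <- igraph::coreness(und)
  igraph::induced_subgraph(graph, igraph::V(graph)[core >= k])
}

#' Narrative overlap (Venn partition) across tagged users
#'
#' Counts users in each of the seven nonempty subsets of
#' {HCQ, OFFICIALS, PREVENTION} — the exact Venn partition, so a user
#' tagged with all three counts only toward the triple cell — plus the
#' total number of tagged users; percentages of the total are reported to
#' the nearest integer.
#'
#' @param profiles tibble from [build_profiles()] with a `narratives`
#'   column.
#' @return list with `counts` (tibble `subset`, `count`, `percent`) and
#'   `total_tagged`.
#' @export
narrative_overlap <- function(profiles) {
  narrs <- c("HCQ", "OFFICIALS", "PREVENTION")
  tags <- strsplit(profiles$narratives, "|", fixed = TRUE)
  keys <- vapply(tags, function(tg) {
    paste(narrs[narrs %in% tg], collapse = "+")
  }, character(1))
  tagged <- keys[nzchar(keys)]
  total <- length(tagged)
  subsets <- unlist(lapply(1:3, function(sz) {
    combn(narrs, sz, paste, collapse = "+", simplify = FALSE)
  }))
  counts <- unname(vapply(subsets, function(s) sum(tagged == s), integer(1)))
  pct <- if (total > 0) as.integer(round(100 * counts / total)) else
    rep(0L, length(counts))
  list(counts = tibble(subset = unlist(subsets), count = counts,
                       percent = pct),
       total_tagged = total)
}

#' Export a graph as a weighted edge list TSV
#'
#' @param graph igraph with a `weight` edge attribute.
#' @param path output path; columns `src`, `dst`, `weight`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("src", "dst")
  if (!"weight" %in% names(el)) el$weight <- 1
  utils::write.table(el[, c("src", "dst", "weight")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a graph as GraphML for external layout tools
#'
#' Node attributes already on the graph (e.g. lean, narratives) are carried
#' along so force-directed layout and coloring can be done elsewhere.
#'
#' @param graph igraph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
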