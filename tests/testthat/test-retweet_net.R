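test_that("retweets aggregate into weighted information-flow edges", {
  tw <- tiny_tweets(rep("userA", 3), rt_user = "userB",
                    rt_tweet = c("x1", "x2", "x3"))
  pr <- engaged_profiles(c("userA", "userB"))
  g <- build_retweet_graph(tw, pr)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::as_data_frame(g)
  expect_equal(e$from, "userB")  # retweeted -> retweeter
  expect_equal(e$to, "userA")
  expect_equal(e$weight, 3)
})

test_that("non-engaged retweeters contribute no edges", {
  tw <- tiny_tweets(c("userA", "userC"), rt_user = "userB",
                    rt_tweet = c("x1", "x2"))
  pr <- engaged_profiles(c("userA", "userB", "userC"),
                         engaged = c(FALSE, TRUE, FALSE))
  g <- build_retweet_graph(tw, pr)
  expect_equal(igraph::vcount(g), 0)
})

test_that("edge weights match brute-force pair counting on a synthetic stream", {
  tw <- default_stream()
  ctl <- default_catalog()
  pr <- build_profiles(tw, ctl)
  g <- build_retweet_graph(tw, pr)
  engaged <- pr$user_id[pr$misinfo_engaged]
  rts <- tw[!is.na(tw$retweeted_user_id) & tw$user_id %in% engaged &
              tw$retweeted_user_id != tw$user_id, ]
  brute <- table(paste(rts$retweeted_user_id, rts$user_id, sep = "->"))
  el <- igraph::as_data_frame(g)
  expect_equal(igraph::ecount(g), length(brute))
  expect_equal(sort(el$weight),
               sort(as.integer(brute)))
  got <- stats::setNames(el$weight, paste(el$from, el$to, sep = "->"))
  expect_equal(got[names(brute)], stats::setNames(as.numeric(brute),
                                                  names(brute)))
})

test_that("prominence ranks distinct retweeters with id tie-breaks", {
  tw <- tiny_tweets(sprintf("fan%02d", 1:10), rt_user = "hub",
                    rt_tweet = sprintf("x%02d", 1:10))
  pr <- engaged_profiles(c("hub", sprintf("fan%02d", 1:10)))
  g <- build_retweet_graph(tw, pr)
  top <- prominent_users(g, 3)
  expect_equal(top$user_id[1], "hub")
  expect_equal(top$out_degree[1], 10L)
  expect_equal(top$out_degree[2:3], c(0L, 0L))
  expect_equal(top$user_id[2:3], c("fan01", "fan02"))  # id tie-break
  # matches a brute-force adjacency scan on a random directed graph
  set.seed(14)
  from <- sample(sprintf("v%02d", 1:15), 60, TRUE)
  to <- sample(sprintf("v%02d", 1:15), 60, TRUE)
  keep <- from != to
  tw2 <- tiny_tweets(to[keep], rt_user = from[keep],
                     rt_tweet = sprintf("y%03d", seq_len(sum(keep))))
  g2 <- build_retweet_graph(tw2, engaged_profiles(unique(c(from, to))))
  brute <- brute_out_degree(from[keep], to[keep])
  got <- prominent_users(g2, igraph::vcount(g2))
  expect_equal(stats::setNames(got$out_degree, got$user_id)[names(brute)],
               brute)
})

test_that("bot pruning removes heavy tweeters with zero retweeters only", {
  tw <- tiny_tweets(sprintf("fan%02d", 1:5), rt_user = "hub",
                    rt_tweet = sprintf("x%02d", 1:5))
  pr <- engaged_profiles(c("hub", "loudbot", sprintf("fan%02d", 1:5)))
  # loudbot retweets others so it enters the graph, but nobody retweets it
  tw <- dplyr::bind_rows(tw, tiny_tweets("loudbot", rt_user = "hub",
                                         rt_tweet = "x99"))
  tw$tweet_id <- sprintf("tw%03d", seq_len(nrow(tw)))
  g <- build_retweet_graph(tw, pr)
  counts <- c(hub = 10000, loudbot = 10000, fan01 = 3, fan02 = 3, fan03 = 3,
              fan04 = 3, fan05 = 3)
  res <- prune_bots(g, counts, rate_threshold = 1000)
  # hub has 10,000 tweets but is retweeted, so it stays; loudbot goes
  expect_equal(res$removed, "loudbot")
  expect_true("hub" %in% igraph::V(res$graph)$name)
})

test_that("planted bots are exactly the accounts pruned", {
  cfg <- default_config()
  tw <- default_stream()
  pr <- build_profiles(tw, default_catalog())
  tt <- truth_table(cfg)
  g <- build_retweet_graph(tw, pr)
  counts <- original_tweet_counts(tw)
  thr <- 5 * cfg$base_rate * cfg$n_days  # midway between user and bot rates
  res <- prune_bots(g, counts, thr)
  expect_setequal(res$removed, tt$user_id[tt$is_bot])
})

test_that("k-core matches peeling and nests across k", {
  # complete graph: every node survives k = n - 1
  cmpl <- t(utils::combn(5, 2))
  g <- edges_to_igraph(cmpl, 5)
  expect_equal(igraph::vcount(k_core(g, 4)), 5)
  # a tree has no 2-core
  tree <- cbind(1:6, c(2, 3, 4, 5, 6, 7))
  expect_equal(igraph::vcount(k_core(edges_to_igraph(tree, 7), 2)), 0)
  # random graphs against the peeling oracle, plus the nesting property
  set.seed(7)
  for (i in 1:15) {
    n <- sample(10:40, 1)
    edges <- random_edges(n, 0.15)
    gr <- edges_to_igraph(edges, n)
    for (k in 2:3) {
      expect_setequal(igraph::V(k_core(gr, k))$name,
                      sprintf("n%03d", brute_kcore_nodes(edges, n, k)))
    }
    expect_true(all(igraph::V(k_core(gr, 3))$name %in%
                      igraph::V(k_core(gr, 2))$name))
  }
})

test_that("narrative overlap partitions tagged users exactly", {
  pr <- engaged_profiles(sprintf("u%03d", 1:100))
  pr$narratives <- c(rep("HCQ", 10), rep("OFFICIALS", 20),
                     rep("PREVENTION", 30), rep("HCQ|PREVENTION", 15),
                     rep("HCQ|OFFICIALS|PREVENTION", 13), rep("", 12))
  ov <- narrative_overlap(pr)
  expect_equal(ov$total_tagged, 88)
  cts <- stats::setNames(ov$counts$count, ov$counts$subset)
  expect_equal(unname(cts["HCQ"]), 10L)
  expect_equal(unname(cts["HCQ+PREVENTION"]), 15L)
  expect_equal(unname(cts["HCQ+OFFICIALS+PREVENTION"]), 13L)
  expect_equal(unname(cts["HCQ+OFFICIALS"]), 0L)
  expect_equal(sum(ov$counts$count), ov$total_tagged)  # conservation
  expect_equal(unname(ov$counts$percent[ov$counts$subset ==
                                          "HCQ+OFFICIALS+PREVENTION"]),
               15L)  # 13/88 = 14.8 -> 15
  # empty case
  pr$narratives <- ""
  ov0 <- narrative_overlap(pr)
  expect_equal(ov0$total_tagged, 0)
  expect_true(all(ov0$counts$count == 0))
})
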