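test_that("tokenization reduces a tweet the expected way", {
  toks <- tokenize_text(
    "Thousands of new #covid cases reported in Los Angeles County!!",
    drop_stopwords = TRUE)[[1]]
  expect_equal(toks, c("thousands", "new", "covid", "cases", "reported",
                       "los", "angeles", "county"))
})

test_that("bigram extraction matches a brute-force count on a tiny corpus", {
  tw <- tiny_tweets(
    rep("u", 4),
    day = c(1, 1, 8, 8))
  tw$text <- c("covid cases rising fast",
               "new covid cases reported",
               "covid cases surge worldwide",
               "vaccine rollout begins")
  bs <- extract_bigrams(tw, top_n = 100)
  expect_equal(unname(bs$counts["covid cases", 1]), 2L)
  expect_equal(unname(bs$counts["covid cases", 2]), 1L)
  # week 1 has 3+3=6 bigram tokens, week 2 has 3+2=5
  expect_equal(bs$weekly_totals, c(6L, 5L))
  expect_equal(unname(bs$freq["covid cases", ]), c(2 / 6, 1 / 5))
  # all-stopword or single-token texts contribute nothing
  tw$text <- c("the of and", "a", "is was", "to")
  expect_length(extract_bigrams(tw, 10)$bigrams, 0)
})

test_that("top_n keeps the most frequent bigrams deterministically", {
  tw <- default_stream()
  bs1 <- extract_bigrams(tw, top_n = 1)
  full <- extract_bigrams(tw, top_n = 10000)
  totals <- rowSums(full$counts)
  expect_equal(bs1$bigrams, names(totals)[which.max(totals)])
  # weekly normalization checked against the brute-force totals
  expect_equal(full$freq, sweep(full$counts, 2, pmax(full$weekly_totals, 1),
                                "/"))
})

test_that("burst filter drops flat series and is scale invariant", {
  weeks <- seq(as.Date("2020-03-02"), by = 7, length.out = 52)
  flat <- matrix(rep(5, 52), 1, dimnames = list("covid 19", NULL))
  bursty <- matrix(c(rep(0, 20), 40, 80, 40, rep(0, 29)), 1,
                   dimnames = list("lab leak", NULL))
  mk <- function(m) {
    structure(list(bigrams = rownames(m), weeks = weeks,
                   counts = m, freq = m / 1000,
                   weekly_totals = rep(1000L, 52)),
              class = "bigram_series")
  }
  both <- mk(rbind(flat, bursty))
  cl <- shape_cluster(both, k = 1, window_days = 21, burst_fraction = 0.5)
  expect_equal(attr(cl, "filtered"), "covid 19")
  expect_equal(cl$members[[1]], "lab leak")
  # scaling a series does not change its filter decision
  scaled <- mk(rbind(flat * 1000, bursty * 0.001))
  cl2 <- shape_cluster(scaled, k = 1, window_days = 21, burst_fraction = 0.5)
  expect_equal(attr(cl2, "filtered"), "covid 19")
  # k larger than the survivors errors with counts
  expect_error(shape_cluster(both, k = 5), "surviv",
               class = "misinfo_config_error")
})

test_that("identical series land in one cluster; order does not matter", {
  weeks <- seq(as.Date("2020-03-02"), by = 7, length.out = 20)
  bump <- function(p) exp(-0.5 * ((1:20 - p) / 1.5)^2)
  m <- rbind("a b" = bump(4), "c d" = bump(4),
             "e f" = bump(12), "g h" = bump(12.5))
  series <- structure(list(bigrams = rownames(m), weeks = weeks,
                           counts = m, freq = m,
                           weekly_totals = rep(1L, 20)),
                      class = "bigram_series")
  cl <- shape_cluster(series, k = 2, seed = 5)
  expect_equal(cl$members[[1]], c("a b", "c d"))
  expect_equal(cl$members[[2]], c("e f", "g h"))
  expect_true(cl$peak_week[1] < cl$peak_week[2])  # ordered by peak
  # permuting input rows changes nothing but ids
  perm <- c(3, 1, 4, 2)
  series2 <- structure(list(bigrams = rownames(m)[perm], weeks = weeks,
                            counts = m[perm, ], freq = m[perm, ],
                            weekly_totals = rep(1L, 20)),
                       class = "bigram_series")
  cl2 <- shape_cluster(series2, k = 2, seed = 5)
  expect_identical(cl$members, cl2$members)
})

test_that("topic model picks the separable structure and is deterministic", {
  set.seed(31)
  vocabA <- paste0("alpha", 1:15)
  vocabB <- paste0("beta", 1:15)
  docs <- c(replicate(60, paste(sample(vocabA, 8, TRUE), collapse = " ")),
            replicate(60, paste(sample(vocabB, 8, TRUE), collapse = " ")))
  tw <- tibble::tibble(text = docs)
  tm <- topic_model(tw, c(2, 5), seed = 4)
  expect_equal(tm$chosen_n, 2)
  # the two topics separate the vocabularies
  t1 <- tm$topics[[1]]; t2 <- tm$topics[[2]]
  expect_true(all(startsWith(t1, "alpha")) || all(startsWith(t1, "beta")))
  expect_true(all(startsWith(t2, "alpha")) || all(startsWith(t2, "beta")))
  expect_false(startsWith(t1[1], substr(t2[1], 1, 4)))
  expect_identical(tm, topic_model(tw, c(2, 5), seed = 4))
  # a single candidate is returned without comparison
  tm1 <- topic_model(tw, 1, seed = 4)
  expect_equal(tm1$chosen_n, 1)
  expect_error(topic_model(tw[1:10, ], 2), class = "misinfo_config_error")
})
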