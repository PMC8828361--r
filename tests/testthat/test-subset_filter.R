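test_that("misinformation subset keeps exactly tweets with unreliable URLs", {
  ctl <- tiny_catalog()
  tw <- tiny_tweets(
    c("u1", "u2", "u3", "u4"),
    urls = list("https://reliable-left.com/x",
                c("https://questionable.org/a", "https://reliable-left.com/b"),
                "https://www.conspiracysite.com/p",
                character())
  )
  ms <- misinfo_subset(tw, ctl)
  expect_equal(ms$user_id, c("u2", "u3"))  # >=1 rule, order preserved
  expect_equal(attr(ms, "n_kept"), 2)
  expect_equal(attr(ms, "n_total"), 4)
})

test_that("zero misinformation propensity yields an empty subset", {
  cfg <- synth_config(n_users = 40, n_days = 14, misinfo_propensity = 0,
                      seed = 9)
  tw <- generate_stream(cfg)
  expect_equal(nrow(misinfo_subset(tw, synth_catalog(cfg))), 0)
})

test_that("subset membership is monotone under appending tweets", {
  ctl <- default_catalog()
  tw <- default_stream()
  half <- misinfo_subset(utils::head(tw, 2000), ctl)
  full <- misinfo_subset(tw, ctl)
  expect_true(all(half$tweet_id %in% full$tweet_id))
})

test_that("narrative tagging matches tokens, prefixes, and phrases", {
  expect_equal(unname(unlist(tag_narratives("HCQ works!"))), "HCQ")
  expect_setequal(tag_narratives("Fauci and the CDC lied about masks")[[1]],
                  c("OFFICIALS", "PREVENTION"))
  expect_equal(
    unname(unlist(tag_narratives("practice social distancing and get a vaccine"))),
    "PREVENTION")
  # token matching refuses substrings; the substring mode accepts them
  expect_length(tag_narratives("big protest today")[[1]], 0)
  expect_equal(unname(unlist(tag_narratives("big protest today",
                                            substring = TRUE))),
               "PREVENTION")
  # hashtag forms match their plain-word token
  expect_equal(unname(unlist(tag_narratives("take #hcq now"))), "HCQ")
  expect_length(tag_narratives("nothing relevant here")[[1]], 0)
  # output never contains a name absent from the specs
  specs <- list(narrative_spec("ONLY", "mask"))
  out <- tag_narratives(c("mask up", "hcq rules"), specs)
  expect_true(all(unlist(out) %in% "ONLY"))
})

test_that("narrative specs validate their patterns", {
  expect_error(narrative_spec("X", character()),
               class = "misinfo_config_error")
  expect_error(narrative_spec("X", "Mask"), class = "misinfo_config_error")
  expect_error(tag_narratives("x", specs = list()),
               class = "misinfo_config_error")
})

test_that("top hashtags count case-insensitively with lexicographic ties", {
  tw <- tiny_tweets(rep("u", 4),
                    hashtags = list(c("CovidHoax", "b"), c("covidhoax", "b"),
                                    c("covidhoax", "a"), c("a", "c")))
  top <- top_hashtags(tw, 2)
  expect_equal(top$hashtag, c("covidhoax", "a"))
  expect_equal(top$count, c(3L, 2L))
  # tie broken lexicographically: a before b at equal counts
  top3 <- top_hashtags(tw, 3)
  expect_equal(top3$hashtag[2:3], c("a", "b"))
  expect_equal(nrow(top_hashtags(tiny_tweets("u"), 5)), 0)
  expect_error(top_hashtags(tw, 0), class = "misinfo_config_error")
})

test_that("top hashtags agree with a brute-force counter on synthetic data", {
  tw <- default_stream()
  top <- top_hashtags(tw, 10)
  tags <- tolower(unlist(tw$hashtags))
  brute <- sort(table(tags), decreasing = TRUE)
  expect_equal(sum(top$count), sum(utils::head(sort(as.integer(brute),
                                                    decreasing = TRUE), 10)))
  expect_equal(top$count[1], max(brute))
})

test_that("volume curves bin, zero-fill, and smooth with the prefix rule", {
  # constant series is a fixed point of the smoother
  tw <- tiny_tweets(rep("u", 15), day = rep(1:3, each = 5))
  vc <- volume_curve(tw, "day", window = 7)
  expect_equal(vc$count, rep(5L, 3))
  expect_equal(vc$smoothed, rep(5, 3))
  # single tweet mid-span with window 1: counts pass through, zero-filled
  tw2 <- tiny_tweets(c("u", "u"), day = c(1, 5))
  vc2 <- volume_curve(tw2[2:2, ] |> dplyr::bind_rows(tw2[1:1, ]), "day", 1)
  expect_equal(vc2$count, c(1L, 0L, 0L, 0L, 1L))
  expect_equal(vc2$smoothed, c(1, 0, 0, 0, 1))
  # prefix means: counts 7,0,14 with window 7 smooth to 7/1, 7/2, 21/3
  tw3 <- tiny_tweets(rep("u", 21), day = c(rep(1, 7), rep(3, 14)))
  vc3 <- volume_curve(tw3, "day", 7)
  expect_equal(vc3$count, c(7L, 0L, 14L))
  expect_equal(vc3$smoothed, c(7, 3.5, 7))
  # conservation: bin counts sum to binned tweets
  vc4 <- volume_curve(default_stream(), "day", 7)
  expect_equal(sum(vc4$count), nrow(default_stream()))
  vc5 <- volume_curve(default_stream(), "week", 7)
  expect_equal(sum(vc5$count), nrow(default_stream()))
  # weekly bins anchor on Monday
  expect_true(all(lubridate::wday(vc5$date, week_start = 1) == 1))
  expect_equal(nrow(volume_curve(tiny_tweets(character()), "day", 7)), 0)
})
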