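# Shared fixtures, built in code. The default stream is generated once per
# test run and reused by several files.

.fixture_env <- new.env(parent = emptyenv())

default_config <- function() {
  synth_config(n_users = 150, n_days = 30, n_bot_users = 5,
               misinfo_propensity = 0.3, trend_slope_questionable = 1,
               n_domains_per_group = 25, seed = 42)
}

default_stream <- function() {
  if (is.null(.fixture_env$stream)) {
    .fixture_env$stream <- generate_stream(default_config())
  }
  .fixture_env$stream
}

default_catalog <- function() synth_catalog(default_config())

# A hand-built miniature stream for exact-arithmetic tests.
tiny_tweets <- function(user_id, text = "hello world", urls = NULL,
                        hashtags = NULL, day = 1, rt_user = NA_character_,
                        rt_tweet = NA_character_) {
  n <- length(user_id)
  tibble::tibble(
    tweet_id = sprintf("tw%03d", seq_len(n)),
    user_id = user_id,
    timestamp = as.POSIXct("2020-03-01 12:00:00", tz = "UTC") +
      (rep_len(day, n) - 1) * 86400 + seq_len(n),
    text = rep_len(text, n),
    lang = "en",
    urls = if (is.null(urls)) rep(list(character()), n) else urls,
    hashtags = if (is.null(hashtags)) rep(list(character()), n) else hashtags,
    retweeted_user_id = rep_len(rt_user, n),
    retweeted_tweet_id = rep_len(rt_tweet, n)
  )
}

# Minimal profile table marking users as misinformation-engaged.
engaged_profiles <- function(user_ids, engaged = TRUE) {
  tibble::tibble(user_id = user_ids, n_urls = 10L, left = 0L,
                 left_center = 0L, least = 0L, right_center = 0L, right = 0L,
                 lean = "unclassified",
                 misinfo_engaged = rep_len(engaged, length(user_ids)),
                 narratives = "")
}

tiny_catalog <- function() {
  tibble::tibble(
    domain = c("conspiracysite.com", "questionable.org", "reliable-left.com",
               "reliable-right.com", "neutralwire.com"),
    reliability = c("conspiracy", "questionable", "reliable", "reliable",
                    "reliable"),
    bias = c("right", "right_center", "left", "right", "least")
  )
}
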