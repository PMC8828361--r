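#' Configuration for the synthetic tweet-stream generator
#'
#' Bundles and validates every knob of the generator. The generator emulates,
#' at desk scale, the statistical structure the downstream analysis assumes of
#' a platform stream: political homophily in domain sharing and retweeting,
#' a per-URL propensity to share unreliable (conspiracy/questionable) sources,
#' planted linear growth in daily unreliable-URL volume, bursty bigram topics,
#' and hyperactive bot accounts that are never retweeted.
#'
#' @param n_users number of regular (non-bot) accounts.
#' @param n_domains_per_group number of domains in each unreliable group
#'   (conspiracy, questionable). Mainstream pools (reliable-left,
#'   reliable-right, neutral) hold `mainstream_factor` times as many domains,
#'   emulating the long tail of ordinary news domains against which a random
#'   baseline sample is sparse.
#' @param n_days length of the simulated period in days (minimum 14).
#' @param base_rate mean original tweets per regular user per day.
#' @param lean_mix probability a user's latent political lean is right
#'   (vs left).
#' @param fidelity probability a mainstream (non-misinformation) shared
#'   domain matches the sharer's latent lean; the complement goes to the
#'   opposite lean's pool. Must be at least 0.5.
#' @param misinfo_propensity probability that any single shared URL comes
#'   from an unreliable group (split evenly conspiracy/questionable).
#' @param trend_slope_conspiracy,trend_slope_questionable planted additional
#'   unreliable URLs per day: on day `d` (0-based) an extra
#'   `Poisson(slope * d)` tweets each carrying one URL from the group are
#'   injected, so the expected daily count is affine in `d` with this slope.
#' @param retweet_homophily probability a retweet target is drawn from
#'   same-lean users' earlier tweets.
#' @param retweet_rate probability a tweet (after day 0) is a retweet.
#' @param n_bot_users number of bot accounts; bots tweet at 10 times
#'   `base_rate` and never appear as retweet targets.
#' @param topic_bursts list of bursty topics, each a list with elements
#'   `peak_day`, `width_days`, `bigrams` (character vector of two-token
#'   phrases) and optional `height` (expected injected tweets per day at the
#'   peak, default 20). Burst tweet volume follows a Gaussian bump around
#'   `peak_day`.
#' @param mainstream_factor multiplier for mainstream pool sizes (see
#'   `n_domains_per_group`).
#' @param seed integer RNG seed; identical config and seed give a
#'   byte-identical stream and truth table.
#' @return object of class `synth_config`.
#' @seealso [generate_stream()], [truth_table()], [synth_catalog()]
#' @export
synth_config <- function(n_users = 200,
                         n_domains_per_group = 20,
                         n_days = 30,
                         base_rate = 1.5,
                         lean_mix = 0.5,
                         fidelity = 0.8,
                         misinfo_propensity = 0.2,
                         trend_slope_conspiracy = 0,
                         trend_slope_questionable = 0,
                         retweet_homophily = 0.8,
                         retweet_rate = 0.3,
                         n_bot_users = 0,
                         topic_bursts = list(),
                         mainstream_factor = 10,
                         seed = 1L) {
  chk_count <- function(x, name, min = 0) {
    if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
      abort(sprintf("`%s` must be a single integer >= %d.", name, min),
            class = "misinfo_config_error")
    }
  }
  chk_prob <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", name),
            class = "misinfo_config_error")
    }
  }
  chk_count(n_users, "n_users")
  chk_count(n_bot_users, "n_bot_users")
  chk_count(n_domains_per_group, "n_domains_per_group", min = 1)
  chk_count(n_days, "n_days", min = 14)
  if (base_rate <= 0) {
    abort("`base_rate` must be positive.", class = "misinfo_config_error")
  }
  for (p in c("lean_mix", "fidelity", "misinfo_propensity",
              "retweet_homophily", "retweet_rate")) {
    chk_prob(get(p), p)
  }
  if (fidelity < 0.5) {
    abort("`fidelity` must be at least 0.5 (homophily strength).",
          class = "misinfo_config_error")
  }
  if (trend_slope_conspiracy < 0 || trend_slope_questionable < 0) {
    abort("Trend slopes must be nonnegative.", class = "misinfo_config_error")
  }
  if (!is.list(topic_bursts)) {
    abort("`topic_bursts` must be a list.", class = "misinfo_config_error")
  }
  topic_bursts <- lapply(topic_bursts, function(b) {
    if (is.null(b$peak_day) || is.null(b$width_days) || is.null(b$bigrams)) {
      abort("Each topic burst needs `peak_day`, `width_days` and `bigrams`.",
            class = "misinfo_config_error")
    }
    if (is.null(b$height)) b$height <- 20
    b
  })
  structure(
    list(n_users = as.integer(n_users),
         n_domains_per_group = as.integer(n_domains_per_group),
         n_days = as.integer(n_days),
         base_rate = base_rate,
         lean_mix = lean_mix,
         fidelity = fidelity,
         misinfo_propensity = misinfo_propensity,
         trend_slope_conspiracy = trend_slope_conspiracy,
         trend_slope_questionable = trend_slope_questionable,
         retweet_homophily = retweet_homophily,
         retweet_rate = retweet_rate,
         n_bot_users = as.integer(n_bot_users),
         topic_bursts = topic_bursts,
         mainstream_factor = as.integer(mainstream_factor),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d users (+%d bots), %d days, base rate %.2f tweets/user/day\n",
              x$n_users, x$n_bot_users, x$n_days, x$base_rate))
  cat(sprintf("  lean mix (right) %.2f, fidelity %.2f, misinfo propensity %.2f\n",
              x$lean_mix, x$fidelity, x$misinfo_propensity))
  cat(sprintf("  planted slopes: conspiracy %.2f, questionable %.2f URLs/day\n",
              x$trend_slope_conspiracy, x$trend_slope_questionable))
  cat(sprintf("  %d topic bursts, seed %d\n", length(x$topic_bursts), x$seed))
  invisible(x)
}

# Domain name pools implied by a config; deterministic (no RNG).
synth_domain_pools <- function(config) {
  n <- config$n_domains_per_group
  m <- config$n_domains_per_group * config$mainstream_factor
  list(
    conspiracy   = sprintf("conspiracy-news-%03d.com", seq_len(n)),
    questionable = sprintf("questionable-news-%03d.com", seq_len(n)),
    left         = sprintf("left-news-%03d.com", seq_len(m)),
    right        = sprintf("right-news-%03d.com", seq_len(m)),
    neutral      = sprintf("neutral-news-%03d.com", seq_len(m))
  )
}

#' Domain catalog implied by a synthetic configuration
#'
#' Returns the credibility/bias catalog for the domains the generator can
#' emit, in the same shape [load_catalog()] produces. Conspiracy domains are
#' labeled right-biased and questionable domains right-center, mirroring the
#' observed skew of low-credibility news ecosystems; mainstream pools carry
#' left / right / least-biased reliable labels.
#'
#' @param config a [synth_config()].
#' @return tibble with columns `domain`, `reliability`, `bias`.
#' @export
synth_catalog <- function(config) {
  pools <- synth_domain_pools(config)
  tibble(
    domain = c(pools$conspiracy, pools$questionable,
               pools$left, pools$right, pools$neutral),
    reliability = c(rep("conspiracy", length(pools$conspiracy)),
                    rep("questionable", length(pools$questionable)),
                    rep("reliable", length(pools$left) + length(pools$right) +
                          length(pools$neutral))),
    bias = c(rep("right", length(pools$conspiracy)),
             rep("right_center", length(pools$questionable)),
             rep("left", length(pools$left)),
             rep("right", length(pools$right)),
             rep("least", length(pools$neutral)))
  )
}

# Size of each user's personal mainstream repertoire per lean side, and the
# probability a mainstream share explores outside the repertoire. Real media
# diets are narrow (a handful of favourite outlets), so two random mainstream
# domains are rarely shared by the same account, while unreliable sources
# circulate community-wide; this asymmetry is what makes the co-sharing
# baseline sparse and the unreliable networks dense.
repertoire_size <- 6L
explore_prob <- 0.1

# Draw user latent labels (and mainstream repertoires); must be the
# generator's first RNG consumption so truth_table() reproduces exactly the
# labels a stream was built from.
draw_users <- function(config) {
  n <- config$n_users
  nb <- config$n_bot_users
  m <- config$n_domains_per_group * config$mainstream_factor
  if (n + nb == 0) {
    return(list(users = tibble(user_id = character(), lean = character(),
                               is_bot = logical(), propensity = double()),
                rep_left = matrix(0L, 0, repertoire_size),
                rep_right = matrix(0L, 0, repertoire_size)))
  }
  leans <- ifelse(runif(n + nb) < config$lean_mix, "right", "left")
  users <- tibble(
    user_id = c(sprintf("u%05d", seq_len(n)),
                if (nb > 0) sprintf("bot%03d", seq_len(nb)) else character()),
    lean = leans,
    is_bot = c(rep(FALSE, n), rep(TRUE, nb)),
    propensity = rep(config$misinfo_propensity, n + nb)
  )
  list(users = users,
       rep_left = matrix(sample.int(m, (n + nb) * repertoire_size,
                                    replace = TRUE),
                         n + nb, repertoire_size),
       rep_right = matrix(sample.int(m, (n + nb) * repertoire_size,
                                     replace = TRUE),
                          n + nb, repertoire_size))
}

#' Ground-truth latent labels behind a synthetic stream
#'
#' Replays only the user-level draws of [generate_stream()] under the same
#' seed, returning the latent lean, bot flag and misinformation propensity of
#' every account in the stream.
#'
#' @param config a [synth_config()].
#' @param seed optional seed override; defaults to `config$seed` so the table
#'   matches `generate_stream(config)`.
#' @return tibble with columns `user_id`, `latent_lean`, `is_bot`,
#'   `propensity`; one row per account.
#' @export
truth_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  drawn <- withr::with_seed(seed, draw_users(config))
  rename(drawn$users, latent_lean = "lean")
}

background_vocab <- c(
  "covid", "cases", "deaths", "virus", "pandemic", "outbreak", "hospital",
  "doctors", "nurses", "patients", "lockdown", "quarantine", "reopening",
  "schools", "economy", "jobs", "relief", "stimulus", "numbers", "surge",
  "wave", "spread", "state", "county", "city", "country", "world", "health",
  "officials", "report", "news", "update", "breaking", "study", "science",
  "data", "chart", "curve", "rising", "falling", "today", "week", "people",
  "community", "response", "measures", "testing", "positive", "negative"
)

hashtag_vocab <- c(
  "covid19", "coronavirus", "pandemic", "vaccine", "hcq", "fauci",
  "lockdown", "masks", "stayhome", "reopen"
)

lang_tags <- c("en", "es", "pt", "fr", "und")
lang_probs <- c(0.70, 0.12, 0.06, 0.06, 0.06)

# Pick one shared domain per URL slot according to the sharing model: with
# prob `propensity` an unreliable group (conspiracy/questionable split
# evenly, uniform over the whole pool — community-wide circulation);
# otherwise a mainstream pool, on the side matching the sharer's lean with
# prob `fidelity` (else the opposite side), drawn from the sharer's narrow
# personal repertoire except for occasional uniform exploration.
draw_domains <- function(user_row, lean, propensity, fidelity, pools, reps) {
  n <- length(user_row)
  if (n == 0) return(character())
  u1 <- runif(n)
  u2 <- runif(n)
  u3 <- runif(n)
  grp <- ifelse(u1 < propensity,
                ifelse(u2 < 0.5, "conspiracy", "questionable"),
                ifelse(u3 < fidelity,
                       lean,
                       ifelse(lean == "right", "left", "right")))
  out <- character(n)
  for (g in c("conspiracy", "questionable")) {
    idx <- which(grp == g)
    if (length(idx) == 0) next
    pool <- pools[[g]]
    out[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  for (g in c("left", "right")) {
    idx <- which(grp == g)
    if (length(idx) == 0) next
    pool <- pools[[g]]
    rep_mat <- if (g == "left") reps$rep_left else reps$rep_right
    explore <- runif(length(idx)) < explore_prob
    dom_idx <- integer(length(idx))
    if (any(explore)) {
      dom_idx[explore] <- sample.int(length(pool), sum(explore),
                                     replace = TRUE)
    }
    if (any(!explore)) {
      slot <- sample.int(repertoire_size, sum(!explore), replace = TRUE)
      dom_idx[!explore] <- rep_mat[cbind(user_row[idx][!explore], slot)]
    }
    out[idx] <- pool[dom_idx]
  }
  out
}

make_urls <- function(domains) {
  if (length(domains) == 0) return(character())
  www <- ifelse(runif(length(domains)) < 0.3, "www.", "")
  sprintf("https://%s%s/p/%d", www, domains,
          sample.int(99999L, length(domains), replace = TRUE))
}

make_texts <- function(n, phrases = NULL) {
  if (n == 0) return(character())
  lens <- sample(4:8, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    toks <- sample(background_vocab, lens[i], replace = TRUE)
    if (!is.null(phrases)) {
      pos <- sample.int(lens[i] + 1L, 1L) - 1L
      toks <- append(toks, phrases[i], after = pos)
    }
    paste(toks, collapse = " ")
  }, character(1))
}

make_hashtags <- function(n) {
  if (n == 0) return(list())
  k <- ifelse(runif(n) < 0.4, sample(1:2, n, replace = TRUE), 0L)
  lapply(k, function(ki) {
    if (ki == 0) character() else sample(hashtag_vocab, ki)
  })
}

#' Generate a synthetic tweet stream
#'
#' Emits a tweet-record tibble (the schema of [read_tweets()]) with planted
#' structure: homophilous domain sharing and retweeting, a per-URL
#' misinformation propensity, linear growth in daily unreliable-URL counts
#' (plus Poisson noise), Gaussian-bump bursty bigram topics, and bot accounts
#' that tweet at ten times the base rate and are never retweeted. Timestamps
#' are UTC with uniform within-day jitter; the stream is sorted so timestamps
#' are nondecreasing, and every retweet points at an original tweet from an
#' earlier day, so retweet references are always resolvable within the
#' stream. Identical config and seed reproduce the stream byte for byte.
#'
#' @param config a [synth_config()].
#' @return tibble with columns `tweet_id`, `user_id`, `timestamp` (POSIXct
#'   UTC), `text`, `lang`, `urls` (list of character), `hashtags` (list of
#'   character), `retweeted_user_id`, `retweeted_tweet_id` (NA for
#'   originals).
#' @export
generate_stream <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_stream_impl(config))
}

generate_stream_impl <- function(config) {
  drawn <- draw_users(config)
  users <- drawn$users
  pools <- synth_domain_pools(config)
  day0 <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC")
  empty <- tibble(
    tweet_id = character(), user_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    text = character(), lang = character(),
    urls = list(), hashtags = list(),
    retweeted_user_id = character(), retweeted_tweet_id = character()
  )
  if (nrow(users) == 0) return(empty)

  regular <- users[!users$is_bot, ]
  # growing pool of retweetable originals (non-bot authors only)
  cand_id <- character(); cand_user <- character(); cand_lean <- character()
  cand_text <- character(); cand_lang <- character()
  cand_urls <- list(); cand_tags <- list()

  days_out <- vector("list", config$n_days)
  id_counter <- 0L
  rates <- config$base_rate * ifelse(users$is_bot, 10, 1)

  for (d in seq_len(config$n_days) - 1L) {
    n_per_user <- rpois(nrow(users), rates)
    n_tw <- sum(n_per_user)
    uidx <- rep.int(seq_len(nrow(users)), n_per_user)

    can_rt <- length(cand_id) > 0
    is_rt <- can_rt & (runif(n_tw) < config$retweet_rate)

    # --- originals -------------------------------------------------------
    o <- which(!is_rt)
    n_o <- length(o)
    o_user <- users$user_id[uidx[o]]
    o_lean <- users$lean[uidx[o]]
    n_urls <- if (n_o > 0) {
      sample(0:2, n_o, replace = TRUE, prob = c(0.35, 0.45, 0.20))
    } else integer()
    url_lean <- rep.int(o_lean, n_urls)
    url_user_row <- rep.int(uidx[o], n_urls)
    doms <- draw_domains(url_user_row, url_lean, config$misinfo_propensity,
                         config$fidelity, pools, drawn)
    url_str <- make_urls(doms)
    o_urls <- rep(list(character()), n_o)
    if (sum(n_urls) > 0) {
      grpd <- split(url_str, rep.int(seq_len(n_o), n_urls))
      o_urls[as.integer(names(grpd))] <- grpd
    }
    o_text <- make_texts(n_o)
    o_tags <- make_hashtags(n_o)
    o_lang <- if (n_o > 0) {
      sample(lang_tags, n_o, replace = TRUE, prob = lang_probs)
    } else character()

    # --- planted linear trend: extra single-URL unreliable tweets --------
    ex_user <- character(); ex_urls <- list()
    for (g in c("conspiracy", "questionable")) {
      slope <- if (g == "conspiracy") config$trend_slope_conspiracy
               else config$trend_slope_questionable
      if (slope > 0 && nrow(regular) > 0) {
        n_ex <- rpois(1, slope * d)
        if (n_ex > 0) {
          ex_user <- c(ex_user,
                       regular$user_id[sample.int(nrow(regular), n_ex,
                                                  replace = TRUE)])
          dom <- pools[[g]][sample.int(length(pools[[g]]), n_ex,
                                       replace = TRUE)]
          ex_urls <- c(ex_urls, as.list(make_urls(dom)))
        }
      }
    }
    n_ex <- length(ex_user)
    ex_text <- make_texts(n_ex)

    # --- bursty bigram topics -------------------------------------------
    b_user <- character(); b_text <- character()
    for (b in config$topic_bursts) {
      if (nrow(regular) == 0) break
      lam <- b$height * exp(-0.5 * ((d - b$peak_day) / b$width_days)^2)
      n_b <- rpois(1, lam)
      if (n_b > 0) {
        b_user <- c(b_user,
                    regular$user_id[sample.int(nrow(regular), n_b,
                                               replace = TRUE)])
        phr <- b$bigrams[sample.int(length(b$bigrams), n_b, replace = TRUE)]
        b_text <- c(b_text, make_texts(n_b, phrases = phr))
      }
    }
    n_b <- length(b_user)

    # --- retweets --------------------------------------------------------
    r <- which(is_rt)
    n_r <- length(r)
    r_user <- users$user_id[uidx[r]]
    r_lean <- users$lean[uidx[r]]
    tgt <- integer(n_r)
    if (n_r > 0) {
      homo <- runif(n_r) < config$retweet_homophily
      for (ln in c("left", "right")) {
        pool_idx <- which(cand_lean == ln)
        rows <- which(homo & r_lean == ln)
        if (length(rows) > 0) {
          if (length(pool_idx) > 0) {
            tgt[rows] <- pool_idx[sample.int(length(pool_idx), length(rows),
                                             replace = TRUE)]
          } else {
            homo[rows] <- FALSE
          }
        }
      }
      rows <- which(!homo)
      if (length(rows) > 0) {
        tgt[rows] <- sample.int(length(cand_id), length(rows), replace = TRUE)
      }
    }
    # a self-retweet target degenerates the row to an original-like tweet;
    # drop such rows (rare) to keep the no-self-loop invariant simple
    if (n_r > 0) {
      keep <- cand_user[tgt] != r_user
      r_user <- r_user[keep]; tgt <- tgt[keep]; n_r <- length(r_user)
    }

    # --- assemble the day ------------------------------------------------
    day_user <- c(o_user, ex_user, b_user, r_user)
    n_day <- length(day_user)
    if (n_day == 0) { days_out[[d + 1L]] <- empty; next }
    day_text <- c(o_text, ex_text, b_text, cand_text[tgt])
    day_urls <- c(o_urls, ex_urls, rep(list(character()), n_b), cand_urls[tgt])
    day_tags <- c(o_tags, rep(list(character()), n_ex + n_b), cand_tags[tgt])
    day_lang <- c(o_lang, rep("en", n_ex + n_b), cand_lang[tgt])
    day_rt_user <- c(rep(NA_character_, n_o + n_ex + n_b), cand_user[tgt])
    day_rt_id <- c(rep(NA_character_, n_o + n_ex + n_b), cand_id[tgt])

    secs <- runif(n_day) * 86400
    ord <- order(secs)
    ids <- sprintf("t%08d", id_counter + seq_len(n_day))
    id_counter <- id_counter + n_day

    day <- tibble(
      tweet_id = ids,
      user_id = day_user[ord],
      timestamp = day0 + d * 86400 + secs[ord],
      text = day_text[ord],
      lang = day_lang[ord],
      urls = day_urls[ord],
      hashtags = day_tags[ord],
      retweeted_user_id = day_rt_user[ord],
      retweeted_tweet_id = day_rt_id[ord]
    )
    days_out[[d + 1L]] <- day

    # extend candidate pool with this day's non-bot originals
    is_orig <- is.na(day$retweeted_user_id)
    author_bot <- users$is_bot[match(day$user_id, users$user_id)]
    new <- which(is_orig & !author_bot)
    if (length(new) > 0) {
      cand_id <- c(cand_id, day$tweet_id[new])
      cand_user <- c(cand_user, day$user_id[new])
      cand_lean <- c(cand_lean, users$lean[match(day$user_id[new],
                                                 users$user_id)])
      cand_text <- c(cand_text, day$text[new])
      cand_lang <- c(cand_lang, day$lang[new])
      cand_urls <- c(cand_urls, day$urls[new])
      cand_tags <- c(cand_tags, day$hashtags[new])
    }
  }
  bind_rows(days_out)
}
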