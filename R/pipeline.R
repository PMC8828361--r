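#' Language prevalence table
#'
#' Turns per-language tweet counts into a prevalence table: percent is
#' `100 * count / total`, rounded half-up to 2 decimals (so the printed
#' shares of a count table can be reproduced exactly), sorted by descending
#' count with ties broken by tag.
#'
#' @param lang_counts named numeric vector (language tag -> tweet count).
#' @return tibble with columns `lang`, `count`, `percent`.
#' @examples
#' language_shares(c(en = 928225493, es = 186880167, other = 328765961))
#' @export
language_shares <- function(lang_counts) {
  counts <- as.numeric(lang_counts)
  tags <- names(lang_counts)
  if (is.null(tags) || any(is.na(counts)) || any(counts < 0)) {
    abort("`lang_counts` must be a named vector of nonnegative counts.",
          class = "misinfo_config_error")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort("Total language count must be positive.",
          class = "misinfo_config_error")
  }
  pct <- floor(100 * counts / total * 100 + 0.5) / 100  # round half-up, 2 dp
  tibble(lang = tags, count = counts, percent = pct) |>
    arrange(desc(.data$count), .data$lang)
}

#' Pipeline run configuration
#'
#' Collects the file paths, stage toggles and stage parameters of an
#' end-to-end run. Defaults mirror the original study design: top 50,000
#' bigrams, 11 shape clusters over a 21-day window, a classification
#' threshold of more than 5 shared URLs, the 100-core, source groups of
#' 250 domains, and 7-day / 7-week smoothing windows. Desk-scale runs pass
#' smaller values.
#'
#' @param tweets_path path to the JSONL tweet stream.
#' @param catalog_path path to the domain catalog CSV.
#' @param out_dir output directory (created if missing).
#' @param seed global seed; every stochastic stage derives from it.
#' @param top_n,cluster_k,window_days,min_urls,core_k,group_size stage
#'   parameters (see the stage functions).
#' @param day_window,week_window moving-average windows.
#' @param run_topics toggle for the bigram/shape-cluster stage.
#' @param run_lda toggle for the coherence-selected topic model (fit on a
#'   subsample capped at `lda_max_docs` documents).
#' @param lda_candidates candidate topic counts for the topic model.
#' @param lda_max_docs subsample cap for the topic model.
#' @return object of class `run_config`.
#' @export
run_config <- function(tweets_path, catalog_path, out_dir,
                       seed = 1L,
                       top_n = 50000, cluster_k = 11, window_days = 21,
                       min_urls = 5, core_k = 100, group_size = 250,
                       day_window = 7, week_window = 7,
                       run_topics = TRUE, run_lda = FALSE,
                       lda_candidates = c(2, 4), lda_max_docs = 400) {
  for (p in c("top_n", "cluster_k", "window_days", "min_urls", "core_k",
              "group_size", "day_window", "week_window")) {
    v <- get(p)
    if (length(v) != 1 || is.na(v) || v < 1) {
      abort(sprintf("`%s` must be a positive scalar.", p),
            class = "misinfo_config_error")
    }
  }
  structure(list(tweets_path = tweets_path, catalog_path = catalog_path,
                 out_dir = out_dir, seed = as.integer(seed),
                 top_n = top_n, cluster_k = cluster_k,
                 window_days = window_days, min_urls = min_urls,
                 core_k = core_k, group_size = group_size,
                 day_window = day_window, week_window = week_window,
                 run_topics = run_topics, run_lda = run_lda,
                 lda_candidates = lda_candidates,
                 lda_max_docs = lda_max_docs),
            class = "run_config")
}

#' Run the full misinformation pipeline
#'
#' Executes the stages in dependency order — ingest, misinformation subset
#' and narrative volumes, user profiles, retweet network, co-sharing
#' networks, trends, temporal topics — writing each stage's artifacts under
#' `config$out_dir` plus a machine-readable `summary.json` and a `run.log`.
#' Any stage error aborts with the stage name; artifacts written by earlier
#' stages are preserved. With a fixed seed and inputs the summary is
#' byte-identical across reruns.
#'
#' @param config a [run_config()].
#' @return the summary as a named list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("tweets_path", "catalog_path")) {
    if (!file.exists(config[[p]])) {
      abort(sprintf("Config error: `%s` '%s' does not exist.",
                    p, config[[p]]), class = "misinfo_config_error")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat(sprintf("misinfoscope %s | seed %d\n",
              as.character(utils::packageVersion("misinfoscope")),
              config$seed),
      file = log_path)
  log_line <- function(...) {
    cat(sprintf(...), "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            class = "misinfo_stage_error")
    })
    log_line("stage %-12s ok (%.2fs)", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  summary <- list(schema_version = "1.0", seed = config$seed)

  # ingest -------------------------------------------------------------------
  ing <- stage("ingest", {
    tweets <- read_tweets(config$tweets_path)
    catalog <- load_catalog(config$catalog_path)
    list(tweets = tweets, catalog = catalog)
  })
  tweets <- ing$tweets; catalog <- ing$catalog
  lang_tab <- language_shares(table(tweets$lang))
  summary$ingest <- list(n_tweets = nrow(tweets),
                         skipped_lines = attr(tweets, "skipped_lines"),
                         n_catalog_domains = nrow(catalog),
                         top_languages = head(lang_tab, 10))

  # misinformation subset ----------------------------------------------------
  sub <- stage("subset", {
    ms <- misinfo_subset(tweets, catalog)
    vol <- volume_curve(ms, "day", config$day_window, label = "misinfo")
    write.csv(vol, file.path(config$out_dir, "misinfo_volume.csv"),
              row.names = FALSE)
    tags <- tag_narratives(ms$text)
    ht <- top_hashtags(ms, 10)
    list(ms = ms, tags = tags, hashtags = ht)
  })
  narr_counts <- table(factor(unlist(sub$tags),
                              levels = c("HCQ", "OFFICIALS", "PREVENTION")))
  summary$subset <- list(
    n_misinfo = attr(sub$ms, "n_kept"), n_total = attr(sub$ms, "n_total"),
    narrative_tweets = as.list(setNames(as.integer(narr_counts),
                                        names(narr_counts))),
    top_hashtags = sub$hashtags
  )

  # user profiles ------------------------------------------------------------
  profiles <- stage("profiles", {
    pr <- build_profiles(sub$ms, catalog, min_urls = config$min_urls,
                         seed = config$seed, specs = narrative_specs())
    write_profiles(pr, file.path(config$out_dir, "profiles.csv"))
    pr
  })
  summary$profiles <- list(
    n_users = nrow(profiles),
    n_classified = sum(profiles$lean != "unclassified"),
    lean_counts = as.list(table(profiles$lean)),
    n_misinfo_engaged = sum(profiles$misinfo_engaged)
  )

  # retweet network ----------------------------------------------------------
  net <- stage("retweet_net", {
    g <- build_retweet_graph(tweets, profiles)
    counts <- original_tweet_counts(tweets)
    thr <- as.numeric(stats::quantile(counts, 0.95, names = FALSE))
    pruned <- prune_bots(g, counts, thr)
    core <- k_core(pruned$graph, config$core_k)
    write_edge_list(g, file.path(config$out_dir, "retweet_edges.tsv"))
    lean_attr <- profiles$lean[match(igraph::V(g)$name, profiles$user_id)]
    g_attr <- igraph::set_vertex_attr(g, "lean",
                                      value = ifelse(is.na(lean_attr),
                                                     "unclassified",
                                                     lean_attr))
    narr_attr <- profiles$narratives[match(igraph::V(g)$name,
                                           profiles$user_id)]
    g_attr <- igraph::set_vertex_attr(g_attr, "narratives",
                                      value = ifelse(is.na(narr_attr), "",
                                                     narr_attr))
    write_graphml(g_attr, file.path(config$out_dir, "retweet_net.graphml"))
    list(g = g, pruned = pruned, core = core, threshold = thr)
  })
  ov <- narrative_overlap(profiles)
  summary$retweet_net <- list(
    n_nodes = igraph::vcount(net$g),
    n_ties = igraph::ecount(net$g),
    bot_threshold = net$threshold,
    n_bots_removed = length(net$pruned$removed),
    core_k = config$core_k,
    core_size = igraph::vcount(net$core),
    prominent = if (igraph::vcount(net$g) > 0)
      prominent_users(net$g, min(10, igraph::vcount(net$g))) else NULL,
    narrative_overlap = ov$counts,
    total_tagged = ov$total_tagged
  )

  # co-sharing networks ------------------------------------------------------
  cos <- stage("cosharing", {
    shared <- shared_domains(tweets)
    unrel <- catalog$domain[catalog$reliability %in%
                              c("conspiracy", "questionable")]
    n_cons <- sum(catalog$reliability == "conspiracy")
    n_ques <- sum(catalog$reliability == "questionable")
    k_eff <- min(config$group_size, n_cons, n_ques,
                 length(setdiff(shared, unrel)))
    if (k_eff < 2) abort("Not enough domains to form source groups.")
    grp <- unreliable_groups(catalog, k = k_eff, seed = config$seed)
    rnd <- sample_random_sources(shared, exclude = unrel, k = k_eff,
                                 seed = config$seed)
    gs <- list(conspiracy = build_coshare(tweets, grp$conspiracy),
               questionable = build_coshare(tweets, grp$questionable),
               random = build_coshare(tweets, rnd))
    for (nm in names(gs)) {
      write_edge_list(gs[[nm]],
                      file.path(config$out_dir,
                                sprintf("coshare_%s.tsv", nm)))
    }
    mets <- bind_rows(
      relative_metrics(gs$questionable, gs$random)[1, ],
      relative_metrics(gs$conspiracy, gs$random)
    )
    list(groups = list(conspiracy = grp$conspiracy,
                       questionable = grp$questionable, random = rnd),
         metrics = mets, k_eff = k_eff)
  })
  summary$cosharing <- list(group_size = cos$k_eff, metrics = cos$metrics)

  # trends -------------------------------------------------------------------
  tr <- stage("trends", {
    counts <- daily_counts(tweets, cos$groups)
    write.csv(counts, file.path(config$out_dir, "daily_counts.csv"),
              row.names = FALSE)
    fits <- lapply(c("conspiracy", "questionable"), function(g) {
      fit_trend(counts, g)
    })
    names(fits) <- c("conspiracy", "questionable")
    curve <- weekly_share_curve(counts, config$week_window)
    write.csv(curve, file.path(config$out_dir, "weekly_curve.csv"),
              row.names = FALSE)
    list(fits = fits)
  })
  summary$trends <- lapply(tr$fits, function(f) {
    s <- trend_slope(f)
    list(beta_t = s$estimate, se = s$se, p_value = s$p_value,
         ci = c(s$ci_lo, s$ci_hi),
         beta_baseline =
           f$coefficients$estimate[f$coefficients$term == "v_random"])
  })

  # temporal topics ----------------------------------------------------------
  if (config$run_topics) {
    tp <- stage("topics", {
      bs <- extract_bigrams(tweets, config$top_n)
      cl <- shape_cluster(bs, k = config$cluster_k,
                          window_days = config$window_days,
                          seed = config$seed)
      jsonlite::write_json(
        lapply(seq_len(nrow(cl)), function(i) {
          list(cluster_id = cl$cluster_id[i],
               peak_week = as.character(cl$peak_week[i]),
               members = cl$members[[i]])
        }),
        file.path(config$out_dir, "bigram_clusters.json"),
        auto_unbox = TRUE)
      cl
    })
    summary$topics <- list(
      n_clusters = nrow(tp),
      peak_weeks = as.character(tp$peak_week),
      cluster_sizes = tp$n_members
    )
  }
  if (config$run_lda) {
    lda <- stage("lda", {
      ms <- sub$ms
      docs <- if (nrow(ms) > config$lda_max_docs) {
        withr::with_seed(config$seed,
                         ms[sample.int(nrow(ms), config$lda_max_docs), ])
      } else ms
      topic_model(docs, config$lda_candidates, seed = config$seed,
                  iters = 60)
    })
    summary$lda <- list(chosen_n = lda$chosen_n,
                        coherence = as.list(lda$coherence),
                        topics = lda$topics)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  log_line("done")
  invisible(summary)
}
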