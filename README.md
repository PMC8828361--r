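# misinfoscope

Infodemiology tooling for R: given a stream of tweet-like records and a
catalog of web domains labeled for factual reliability (conspiracy,
questionable, reliable) and political bias (left … right), `misinfoscope`
charts how content from unreliable sources moves through the stream — who
engages with it, which narratives it carries, how its audiences cluster
into echo chambers, and how fast it grows against a random-source baseline.

It is aimed at researchers studying health-misinformation dynamics on
social platforms who have (or can simulate) a keyword-filtered tweet stream
and MBFC-style domain credibility lists.

## What it computes

* **Misinformation subset** — the tweets carrying at least one URL whose
  registered domain is labeled conspiracy or questionable; URL
  normalization is public-suffix aware (`news.bbc.co.uk` → `bbc.co.uk`).
* **Narrative filters** — keyword taggers for three misinformation
  narratives (hydroxychloroquine, US officials/agencies, COVID-19
  prevention), token-based with `*` prefixes, plus smoothed volume curves
  (trailing 7-day / 7-week moving averages) and top-hashtag tables.
* **Temporal topics** — weekly normalized bigram frequency series
  (`count / total bigrams that week`), a burst filter that discards
  perennially trending phrases, and shape-based k-means clustering
  (correlation distance on z-scored series) that orders clusters by peak
  week; optionally a coherence-selected latent topic model.
* **User profiles** — each user's political lean as the majority bias of
  the domains they shared (ties broken uniformly at random; users with
  five or fewer shared URLs left unclassified), and a misinformation
  engagement flag for sharing any unreliable domain.
* **Retweet network** — a directed weighted graph oriented
  retweeted → retweeter (information flow) over misinfo-engaged users,
  out-degree prominence rankings, a bot-pruning rule (tweets frequently,
  never retweeted), k-core decomposition, and narrative Venn overlaps.
* **Domain co-sharing networks** — per source group (conspiracy,
  questionable, random baseline of equal size), domains linked with weight
  equal to the number of distinct users sharing both; density summarized
  by the average local clustering coefficient and the average link weight
  over all possible pairs, absolute and relative to the random baseline.
* **Trends** — daily URL counts per source group and a baseline-adjusted
  OLS fit `V_G ~ t·β₁ + V_R·β₂` (intercept optional), where `t` is the day
  index and `V_R` the random-group volume, with classical standard errors,
  t-tests and 95% CIs.
* **Synthetic generator** — a tweet-stream simulator with planted
  political homophily (in domain sharing and retweeting), per-URL
  misinformation propensity, linear growth trends in unreliable-URL volume,
  Gaussian-bump bursty bigram topics, narrow per-user mainstream
  repertoires (so a random domain baseline is realistically sparse), and
  bot accounts — so the whole pipeline is testable without platform data.

## Worked example

```r
library(misinfoscope)

cfg <- synth_config(n_users = 200, n_days = 30, n_bot_users = 5,
                    misinfo_propensity = 0.3, trend_slope_questionable = 1,
                    n_domains_per_group = 25, seed = 42)
tweets  <- generate_stream(cfg)   # 11,612 tweet records
catalog <- synth_catalog(cfg)

subset <- misinfo_subset(tweets, catalog)
#> misinformation subset: 3118 of 11612 tweets

profiles <- build_profiles(subset, catalog, seed = 1,
                           specs = narrative_specs())
sum(profiles$misinfo_engaged)     # 205 users engaged with misinformation

groups <- unreliable_groups(catalog)
rnd <- sample_random_sources(shared_domains(tweets),
                             exclude = unlist(lapply(groups, `[[`, "domains")),
                             k = 25, seed = 1)
counts <- daily_counts(tweets, list(conspiracy = groups$conspiracy,
                                    questionable = groups$questionable,
                                    random = rnd))
fit_trend(counts, "questionable", include_intercept = TRUE)
#> <trend_fit: questionable over 30 days, with intercept>
#>         term estimate     se     t   p_value   ci_lo  ci_hi
#>  (Intercept)  33.6355 5.5929 6.014 2.039e-06 22.1598 45.111
#>        t_day   1.3968 0.1922 7.266 8.156e-08  1.0023  1.791
#>     v_random   0.8152 0.4696 1.736 9.394e-02 -0.1483  1.779

relative_metrics(build_coshare(tweets, groups$conspiracy),
                 build_coshare(tweets, rnd))
#>        group avg_clustering avg_link_weight rel_clustering rel_link_weight
#> 1 conspiracy          1.000          12.387           2.14              30
#> 2     random          0.468           0.413           1.00               1
```

Reading the output: the questionable-source volume grows by an estimated
1.40 URLs/day (95% CI 1.00–1.79) after adjusting for the random baseline —
above the planted 1.0 because retweets re-amplify the injected trend tweets
— and the conspiracy co-sharing network is 30× denser in average link
weight than an equal-sized random sample of shared domains: the audience
sharing conspiracy domains repeatedly co-shares the same sources.

An end-to-end run over files is one call (or use
`inst/scripts/run_pipeline.R` from a shell):

```r
rc <- run_config("tweets.jsonl", "catalog.csv", "out/", seed = 1,
                 top_n = 500, cluster_k = 4, core_k = 10, group_size = 25)
run_all(rc)   # writes CSV/TSV/GraphML artifacts + out/summary.json
```

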