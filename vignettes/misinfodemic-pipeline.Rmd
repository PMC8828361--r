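---
title: "Charting misinformation dynamics in tweet streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting misinformation dynamics in tweet streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misinfoscope)
```

`misinfoscope` implements a source-credibility approach to misinformation
surveillance: rather than fact-checking individual claims, it treats URLs
pointing at domains with a documented record of publishing conspiracy or
questionable content (MBFC-style labels) as a proxy for misinformation
exposure, and studies the users, narratives, networks and trends around
those shares. This vignette explains each method, its assumptions, the
tunable parameters, and the design decisions taken where the methodology
left choices open.

## The domain catalog and the misinformation subset

All analyses key on the *registered domain* of a shared URL.
`url_to_domain()` lowercases, strips scheme/credentials/port/path, and
collapses subdomains public-suffix-aware, so `news.example.co.uk` and
`www.example.co.uk` both resolve to `example.co.uk`. The multi-label
suffix table is a curated subset of the public-suffix list covering the
country-code suffixes that occur in news catalogs; matching is exact on
the registered domain — no substring matching, so `cdc.gov.fake.com` can
never pass for `cdc.gov`.

`misinfo_subset()` keeps exactly the tweets with at least one URL whose
domain is labeled `conspiracy` or `questionable`. A single unreliable URL
suffices: the subset marks *exposure*, not exclusivity. Unparseable URLs
never match and never abort a stream.

## Narrative tagging

Three narrative filters ship as defaults: HCQ (`hcq`,
`hydroxychloroquine`), OFFICIALS (`fauci`, `brix`, `cdc` — `brix` kept as
published even though it is likely a variant spelling), and PREVENTION
(`mask*`, `vaccine*`, `social distanc*`, `test*`). Matching is
token-based after case-folding and hash-sign stripping: plain keywords
match whole tokens, a trailing `*` matches a token prefix, and multi-word
patterns must match consecutive tokens. A tweet can carry several tags.

The keyword lists were designed for platform-side substring tracking,
where `mask` also catches "masks" and `test` catches "testing" — but raw
substring matching would also tag "protest" for `test`. The default here
is the stricter token semantics, with the prevention keywords in prefix
form to keep their intended coverage; `tag_narratives(substring = TRUE)`
restores verbatim substring behaviour for comparability.

## Volume curves

`volume_curve()` and `weekly_share_curve()` bin by UTC day or ISO week
(Monday-anchored — unambiguous and documented), zero-fill missing bins
across the observed span, and apply a *trailing* moving average (7 days
and 7 weeks by default). The first `window − 1` entries average over the
available prefix, so a constant series is a fixed point of the smoother
and no leading observations are discarded.

## Bigram time series and shape clustering

`extract_bigrams()` tokenizes (lowercase, hash signs stripped, stop words
and single-character fragments dropped — the stop-word list is pinned in
the package so results are exactly reproducible), forms consecutive token
pairs, and keeps the `top_n` most frequent bigrams overall (ties broken
lexicographically). Each retained bigram gets a weekly series of
`count / total bigram tokens that week`; the weekly total counts *all*
bigrams that week, before top-n selection, so a retained series entry is
exactly the bigram's share of that week's bigram traffic.

`shape_cluster()` is a reproducible stand-in for shape-based time-series
clustering of bursty social-media n-grams (the published algorithm's
internals are not specified by this package's sources, so the interface
and the filtering intent are reproduced with standard components):

1. **Burst filter.** A bigram survives only if its best contiguous window
   of `window_days` (rounded to whole weeks; 21 days by default) holds at
   least `burst_fraction` of its total mass (0.5 by default — a
   majority-of-mass reading of "trending for at most three weeks"). This
   removes perennial phrases that would dominate every cluster. The
   criterion is a mass *fraction*, hence scale-invariant. Flat zero-variance
   series are likewise dropped, as they carry no shape.
2. **z-normalization** of survivors, so only shape matters.
3. **k-means with correlation distance**: squared Euclidean distance
   between z-scored series is an affine function of one minus their
   Pearson correlation, so `stats::kmeans` on the z-scored rows *is*
   correlation-distance clustering. Initialization is seeded with 10
   restarts and up to 200 iterations; series are sorted by bigram before
   clustering, so memberships are invariant to input order.

Clusters are reported ordered by the peak week of their mean normalized
series. At full scale the published design used the 50,000 most frequent
bigrams and K = 11; the package's tests run the same machinery on planted
Gaussian-bump topics at `top_n` 20–2,000 and K = 4, sizes chosen so the
suite completes in about two minutes on one CPU.

`topic_model()` provides the coherence-selected topic-model companion: a
compact collapsed-Gibbs LDA (symmetric priors α = 50/K, β = 0.1, 120
sweeps by default) fit for each candidate topic count, scored by mean
UMass coherence of the top 10 terms — chosen because it needs only
document co-occurrence counts, no external corpus — returning the
candidate with the largest coherence. The published analysis selected
N = 4 this way on the full dataset; no attempt is made to reproduce that
number, which is a property of the data, not the method.

## User profiles: political lean and engagement

For each user, `build_profiles()` tallies the registered domains behind
every URL they shared — retweets count, since a retweet republishes the
URL; that reading is a documented choice. The political lean is the bias
class (left, left-center, least, right-center, right) with the most
shares; an exact tie is broken uniformly at random among the tied classes
(ties of three or more classes included) under a caller-supplied seed, and
the draw is consumed *only* for tied users, so perturbing one count
removes the randomness. Users with five or fewer shared URLs — "more than
five" read strictly as ≥ 6 — are left unclassified; the threshold is a
parameter. URLs resolving to uncataloged domains count toward the URL
filter but never toward bias counts (switchable via `count_uncataloged`).
Engagement is deliberately liberal: one unreliable share sets
`misinfo_engaged`, and nothing unsets it.

## Retweet network

Edges run retweeted → retweeter — the direction information flows — so
"out-degree" counts a user's distinct retweeters and the top of the
`prominent_users()` ranking is the most widely retweeted accounts. The
graph is restricted to retweets *by* misinfo-engaged users, but every such
retweet is kept whether or not that particular retweet carried an
unreliable domain. Bot pruning follows a conjunctive heuristic: original
tweet count at least `rate_threshold` *and* zero retweeters; the pipeline
default threshold is the 95th percentile of per-user tweet counts, since
"tweets frequently" is otherwise undefined. `k_core()` uses the standard
unweighted core on the undirected simplification (each neighbor counted
once); the published figures used the 100-core, which is only reachable at
full scale — on desk-scale fixtures the tests exercise small k against a
peeling oracle instead.

## Domain co-sharing networks

For a source group (conspiracy, questionable, or a random baseline of the
same cardinality — 250 at full scale), `build_coshare()` links two domains
with weight equal to the number of *distinct* users who shared both;
share multiplicity is deliberately ignored. Density is summarized two
ways: the mean local clustering coefficient on the binarized graph (nodes
with fewer than two neighbors contribute zero) and the average link
weight over *all possible* pairs, absent links counting zero. The
all-pairs denominator is the reading under which a near-empty baseline
network scores near zero — the published baseline value of 0.01 is only
plausible this way — and an existing-links-only variant sits behind a
flag. The random baseline excludes the unreliable lists, since it serves
as their comparison group. `relative_metrics()` reports target/baseline
ratios with the baseline pinned at exactly 1, and refuses a zero-density
baseline rather than dividing by it.

## Trend estimation

`fit_trend()` regresses a group's daily URL count on the day index and the
random group's daily count: `V_G ~ t·β₁ + V_R·β₂`. The intercept is off
by default, matching the model as printed, and a flag turns it on since
the notation may simply elide it; the day index starts at 0 at the first
observed day. Inference is classical OLS: t-distributed tests with
`n − p` degrees of freedom and 95% CIs. Counts are per URL occurrence
(a tweet with two conspiracy URLs counts twice), switchable reading
documented at the counting stage. Degenerate inputs — constant response
or regressor, collinearity — are refused with the offending regressor
named. No autocorrelation-robust errors are attempted; that is out of
scope, as is changepoint detection.

## The synthetic generator

`generate_stream()` emulates, at desk scale, the statistical structure the
analysis assumes of a platform stream. Its defaults are the package's
statement of "realistic study conditions" and are not tuned per analysis:

* **Accounts.** `n_users` regular accounts with latent lean right with
  probability `lean_mix`, plus `n_bot_users` bots that tweet at 10× the
  base rate and never appear as retweet targets. Poisson tweet counts per
  user-day at `base_rate` (1.5/day default).
* **Domain sharing.** Each original tweet carries 0–2 URLs. A URL is
  unreliable with probability `misinfo_propensity`, split evenly between
  the conspiracy and questionable pools and drawn uniformly within the
  pool — unreliable sources circulate community-wide. Otherwise the URL
  is mainstream: it matches the sharer's lean with probability `fidelity`
  and takes the opposite side otherwise, drawn from the user's narrow
  personal repertoire (6 outlets per side) except for 10% uniform
  exploration. The narrow-repertoire/community-circulation asymmetry
  mirrors real media diets and is what makes a random baseline sample of
  mainstream domains sparse while unreliable-source networks are dense —
  the planted echo-chamber signal. Mainstream pools are
  `mainstream_factor` (10×) larger than unreliable pools, emulating the
  mainstream long tail.
* **Trends.** On day `d`, an extra `Poisson(slope · d)` single-URL
  unreliable tweets are injected per group, so expected daily unreliable
  counts are affine in `d` — recoverable by OLS. Retweets copy URLs, so
  with retweeting enabled the *observed* slope exceeds the planted one by
  the amplification factor; estimator-calibration checks therefore
  disable retweet copying.
* **Retweets.** After day 0, a tweet is a retweet with probability
  `retweet_rate` (0.3 — a field-typical share; the rate is a package
  addition since homophily alone fixes no volume). The target is drawn
  from earlier days' originals, from same-lean authors with probability
  `retweet_homophily`; retweets never chain and never target bots.
* **Topics.** Each burst injects tweets at a Gaussian-bump daily rate
  around `peak_day` whose text embeds a literal two-token phrase, against
  background text from a fixed small vocabulary, making cluster purity
  measurable against the ground truth.
* **Reproducibility.** One RNG seeded once; identical config and seed give
  a byte-identical stream, and `truth_table()` replays only the user-level
  draws to expose latent leans, bot flags and propensities.

What the generator does *not* model — realistic language, follower
graphs, deletion dynamics, coordinated campaigns, heavy-tailed user
activity beyond Poisson — bounds what green tests mean: they demonstrate
the pipeline recovers structure *of the planted kind* at the planted
strength, not that real streams contain such structure.

## Numerical and scale choices

Timestamps are UTC with day-granular bucketing (the analyses only use
daily/weekly bins) and uniform within-day jitter. JSONL round-trips
preserve microsecond precision. Percent tables round half-up to two
decimals to match printed-table presentation; narrative-overlap
percentages round to the nearest integer. Test problem sizes — streams of
5–20 thousand tweets, groups of 25–100 domains, 200-seed coverage and
500-simulation calibration runs — were chosen so the whole suite runs in
roughly two minutes on a single CPU while keeping every Monte-Carlo check
comfortably powered.

## Known limitations

Full-scale dataset-level numbers (billions of tweets, the 11 named topic
clusters, absolute co-share densities, published slope magnitudes) are
properties of the original corpus and are out of reach by design; the
package reproduces the *methods* and validates them on planted structure
plus printed-table arithmetic. URL unshortening is assumed done upstream.
Bot handling is the pruning heuristic only — no behavioural bot
detection. The public-suffix table is a curated subset; exotic suffixes
fall back to a two-label registered domain.
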