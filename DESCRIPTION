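Package: misinfoscope
Title: Misinfodemiology Analysis of Credibility-Labeled Social Media Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying health-misinformation
    dynamics in tweet-like social media streams. Given a stream of
    tweet records and a catalog of web domains labeled for factual
    reliability and political bias, the package builds the
    misinformation subset, tags narrative keywords, tracks smoothed
    volume curves, clusters bigram time series by temporal shape,
    profiles users' political lean from the domains they share,
    constructs retweet and domain co-sharing networks (k-cores,
    bot pruning, echo-chamber density statistics), and fits
    baseline-adjusted ordinary least-squares trends in unreliable-source
    volume. A synthetic stream generator with planted homophily,
    growth trends, and bursty topics makes every stage testable
    without access to platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    lubridate,
    jsonlite,
    igraph,
    Matrix,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
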