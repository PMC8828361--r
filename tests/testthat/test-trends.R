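groups3 <- function(cfg) {
  ctl <- synth_catalog(cfg)
  pools <- list(
    conspiracy = sort(ctl$domain[ctl$reliability == "conspiracy"]),
    questionable = sort(ctl$domain[ctl$reliability == "questionable"])
  )
  list(conspiracy = source_group("conspiracy", pools$conspiracy),
       questionable = source_group("questionable", pools$questionable),
       random = source_group("random",
                             sort(ctl$domain[ctl$bias == "least"])[1:25]))
}

test_that("daily counts tally URL occurrences per group with zero fill", {
  grp <- list(conspiracy = source_group("conspiracy", "conspiracysite.com"),
              random = source_group("random", "neutralwire.com"))
  tw <- tiny_tweets(
    c("u1", "u2"), day = c(1, 3),
    urls = list(c("https://conspiracysite.com/a",
                  "https://conspiracysite.com/b"),
                "https://neutralwire.com/x"))
  dc <- daily_counts(tw, grp)
  expect_equal(nrow(dc), 3)  # missing middle day filled
  expect_equal(dc$conspiracy, c(2L, 0L, 0L))  # two URLs, one tweet
  expect_equal(dc$random, c(0L, 0L, 1L))
  expect_equal(nrow(daily_counts(tiny_tweets(character()), grp)), 0)
})

test_that("daily counts match a brute-force tally on a synthetic stream", {
  cfg <- default_config()
  tw <- default_stream()
  grp <- groups3(cfg)
  dc <- daily_counts(tw, grp)
  doms <- url_to_domain(unlist(tw$urls))
  ddays <- rep(as.Date(tw$timestamp), lengths(tw$urls))
  for (nm in names(grp)) {
    brute <- table(factor(as.character(ddays[doms %in% grp[[nm]]$domains]),
                          levels = as.character(dc$date)))
    expect_equal(dc[[nm]], as.integer(brute))
  }
})

test_that("noiseless linear data is recovered to machine precision", {
  t_idx <- 0:29
  vr <- 10 + (t_idx %% 5)
  counts <- tibble::tibble(date = as.Date("2020-03-01") + t_idx,
                           conspiracy = 3 * t_idx + 2 * vr,
                           random = vr)
  fit <- suppressWarnings(fit_trend(counts, "conspiracy"))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "t_day"],
               3, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "v_random"],
               2, tolerance = 1e-12)
  # CIs contain the point estimates
  expect_true(all(fit$coefficients$ci_lo <= fit$coefficients$estimate &
                    fit$coefficients$estimate <= fit$coefficients$ci_hi))
})

test_that("degenerate inputs are refused by name", {
  t_idx <- 0:29
  base <- tibble::tibble(date = as.Date("2020-03-01") + t_idx,
                         conspiracy = rep(0, 30),
                         random = 10 + (t_idx %% 5))
  expect_error(fit_trend(base, "conspiracy"),
               class = "misinfo_degenerate_error")
  const_vr <- base
  const_vr$conspiracy <- 3 * t_idx
  const_vr$random <- rep(7, 30)
  expect_error(fit_trend(const_vr, "conspiracy"), "v_random",
               class = "misinfo_degenerate_error")
  expect_error(fit_trend(base[1:5, ], "conspiracy"),
               class = "misinfo_config_error")
  expect_error(fit_trend(base, "nope"), class = "misinfo_config_error")
})

test_that("residuals are orthogonal to the regressors", {
  withr::with_seed(5, {
    t_idx <- 0:59
    vr <- rpois(60, 50)
    counts <- tibble::tibble(date = as.Date("2020-03-01") + t_idx,
                             conspiracy = rpois(60, 20 + 2 * t_idx + vr),
                             random = vr)
  })
  fit <- fit_trend(counts, "conspiracy")
  res <- stats::residuals(fit$fit)
  expect_lt(abs(sum(res * t_idx)), 1e-6 * sqrt(sum(res^2) * sum(t_idx^2)))
  expect_lt(abs(sum(res * counts$random)),
            1e-6 * sqrt(sum(res^2) * sum(counts$random^2)))
})

test_that("shifting the day origin changes only the intercept", {
  withr::with_seed(8, {
    t_idx <- 0:39
    vr <- rpois(40, 40)
    y <- rpois(40, 30 + 3 * t_idx + vr)
  })
  c1 <- tibble::tibble(date = as.Date("2020-03-01") + t_idx,
                       conspiracy = y, random = vr)
  c2 <- c1
  c2$date <- c2$date + 100  # same data, shifted origin
  f1 <- fit_trend(c1, "conspiracy", include_intercept = TRUE)
  f2 <- fit_trend(c2, "conspiracy", include_intercept = TRUE)
  s1 <- trend_slope(f1); s2 <- trend_slope(f2)
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-10)
})

test_that("weekly curves compose weekly sums with the trailing mean", {
  cfg <- default_config()
  dc <- daily_counts(default_stream(), groups3(cfg))
  wc <- weekly_share_curve(dc, window_weeks = 3)
  # brute force for one group
  week <- lubridate::floor_date(dc$date, "week", week_start = 1)
  brute <- tapply(dc$questionable, week, sum)
  got <- wc[wc$label == "questionable", ]
  expect_equal(got$count, as.integer(brute))
  sm <- vapply(seq_along(brute), function(i) {
    mean(brute[max(1, i - 2):i])
  }, double(1))
  expect_equal(got$smoothed, unname(sm))
  # constant daily counts give a flat smoothed curve on full weeks
  flat <- tibble::tibble(date = as.Date("2020-03-02") + 0:27,  # 4 ISO weeks
                         conspiracy = rep(2L, 28), random = rep(1L, 28))
  wf <- weekly_share_curve(flat, 7)
  expect_true(all(wf$smoothed[wf$label == "conspiracy"] == 14))
})
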