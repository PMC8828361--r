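#' Daily URL-share counts per source group
#'
#' Counts, per UTC day and per group, the URL occurrences resolving to a
#' group domain (each URL occurrence in a tweet counts once, so a tweet
#' with two conspiracy URLs contributes two). Days with no shares are
#' filled with zero across the observed span of the stream.
#'
#' @param tweets tweet tibble.
#' @param groups named list of [source_group()]s (conventionally
#'   conspiracy, questionable, random).
#' @return tibble with a `date` column and one count column per group;
#'   empty if the stream is empty.
#' @export
daily_counts <- function(tweets, groups) {
  if (nrow(tweets) == 0) {
    return(tibble(date = as.Date(character())))
  }
  n_url_tw <- lengths(tweets$urls)
  df <- tibble(
    date = rep(lubridate::as_date(tweets$timestamp), n_url_tw),
    domain = url_to_domain(unlist(tweets$urls, use.names = FALSE))
  )
  span <- seq(min(lubridate::as_date(tweets$timestamp)),
              max(lubridate::as_date(tweets$timestamp)), by = 1L)
  out <- tibble(date = span)
  for (nm in names(groups)) {
    sub <- df[!is.na(df$domain) & df$domain %in% groups[[nm]]$domains, ]
    cnt <- table(factor(as.character(sub$date), levels = as.character(span)))
    out[[nm]] <- as.integer(cnt)
  }
  out
}

#' Baseline-adjusted OLS trend fit
#'
#' Fits the volume of a tracked group on time, adjusting for the volume of
#' the random baseline: `V_G ~ t * beta_t + V_R * beta_baseline`, ordinary
#' least squares with the intercept off by default (matching the model as
#' printed; a flag turns it on). `t` is the day index starting at 0 at the
#' first observed day, so `beta_t` is the additional URLs per day beyond
#' what the baseline's own growth explains. Classical OLS inference:
#' standard errors, two-sided t-tests with `n - p` degrees of freedom, and
#' 95% confidence intervals.
#'
#' @param counts tibble from [daily_counts()] with at least 10 rows and a
#'   `random` column.
#' @param group name of the column to model (`"conspiracy"` or
#'   `"questionable"`).
#' @param include_intercept fit an intercept as well?
#' @return object of class `trend_fit`: list with `group`, `n_days`,
#'   `coefficients` (tibble term, estimate, se, t, p_value, ci_lo, ci_hi),
#'   and the underlying `lm` fit in `$fit`.
#' @export
fit_trend <- function(counts, group, include_intercept = FALSE) {
  if (!group %in% names(counts)) {
    abort(sprintf("`counts` has no column '%s'.", group),
          class = "misinfo_config_error")
  }
  if (!"random" %in% names(counts)) {
    abort("`counts` needs a 'random' baseline column.",
          class = "misinfo_config_error")
  }
  if (nrow(counts) < 10) {
    abort("Trend fitting needs at least 10 days of data.",
          class = "misinfo_config_error")
  }
  dat <- data.frame(
    y = counts[[group]],
    t_day = as.numeric(counts$date - min(counts$date)),
    v_random = counts$random
  )
  if (sd(dat$y) == 0) {
    abort(sprintf("Response '%s' is constant; nothing to fit.", group),
          class = "misinfo_degenerate_error")
  }
  for (v in c("t_day", "v_random")) {
    if (sd(dat[[v]]) == 0) {
      abort(sprintf("Regressor '%s' is constant.", v),
            class = "misinfo_degenerate_error")
    }
  }
  fml <- if (include_intercept) y ~ t_day + v_random else y ~ 0 + t_day + v_random
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(sprintf("Collinear regressor dropped from the fit: %s.",
                  paste(bad, collapse = ", ")),
          class = "misinfo_degenerate_error")
  }
  sm <- summary(fit)
  ci <- confint(fit, level = 0.95)
  coefs <- tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, 1]),
    se = unname(sm$coefficients[, 2]),
    t = unname(sm$coefficients[, 3]),
    p_value = unname(sm$coefficients[, 4]),
    ci_lo = unname(ci[, 1]),
    ci_hi = unname(ci[, 2])
  )
  structure(list(group = group, n_days = nrow(counts),
                 include_intercept = include_intercept,
                 coefficients = coefs, fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit: %s over %d days%s>\n", x$group, x$n_days,
              if (x$include_intercept) ", with intercept" else ""))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Slope (beta_t) of a trend fit
#' @param fit a `trend_fit`.
#' @return named list with `estimate`, `se`, `p_value`, `ci_lo`, `ci_hi`.
#' @export
trend_slope <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  row <- fit$coefficients[fit$coefficients$term == "t_day", ]
  as.list(row[, c("estimate", "se", "p_value", "ci_lo", "ci_hi")])
}

#' Weekly aggregated, smoothed share curves per group
#'
#' Aggregates daily group counts to ISO weeks (Monday-anchored) and applies
#' a trailing moving average of `window_weeks` (7 in the original design),
#' with the same available-prefix rule as [volume_curve()].
#'
#' @param counts tibble from [daily_counts()].
#' @param window_weeks moving-average window in weeks.
#' @return `volume_series` tibble with columns `label` (group), `date`
#'   (week start), `count`, `smoothed`.
#' @export
weekly_share_curve <- function(counts, window_weeks = 7) {
  if (window_weeks < 1) abort("`window_weeks` must be at least 1.",
                              class = "misinfo_config_error")
  groups <- setdiff(names(counts), "date")
  if (nrow(counts) == 0) {
    out <- tibble(label = character(), date = as.Date(character()),
                  count = integer(), smoothed = double())
    class(out) <- c("volume_series", class(out))
    return(out)
  }
  week <- lubridate::floor_date(counts$date, unit = "week", week_start = 1)
  weeks <- seq(min(week), max(week), by = 7L)
  out <- bind_rows(lapply(groups, function(g) {
    agg <- tapply(counts[[g]], factor(as.character(week),
                                      levels = as.character(weeks)), sum)
    agg[is.na(agg)] <- 0
    tibble(label = g, date = weeks, count = as.integer(agg),
           smoothed = trailing_mean(as.integer(agg), window_weeks))
  }))
  class(out) <- c("volume_series", class(out))
  out
}
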