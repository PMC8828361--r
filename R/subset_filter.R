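#' Filter a stream down to its misinformation subset
#'
#' Keeps exactly the tweets carrying at least one URL whose registered
#' domain the catalog labels conspiracy or questionable, preserving stream
#' order. URLs that fail to parse, or resolve to uncataloged domains, simply
#' never match.
#'
#' @param tweets tweet tibble.
#' @param catalog catalog tibble from [load_catalog()].
#' @return the kept tweets, with attributes `n_kept` and `n_total`.
#' @export
misinfo_subset <- function(tweets, catalog) {
  unreliable <- catalog$domain[catalog$reliability %in%
                                 c("conspiracy", "questionable")]
  keep <- vapply(tweets$urls, function(u) {
    if (length(u) == 0) return(FALSE)
    any(url_to_domain(u) %in% unreliable)
  }, logical(1))
  out <- tweets[keep, ]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_total") <- nrow(tweets)
  out
}

#' Default narrative keyword filters
#'
#' The three misinformation narratives tracked by the pipeline, each defined
#' by a short keyword list: HCQ (hydroxychloroquine and alternative
#' medicines), OFFICIALS (US officials and governing agencies), and
#' PREVENTION (testing, masking, distancing, vaccines). A trailing `*` in a
#' pattern marks token-prefix matching (`social distanc*` matches
#' "social distancing"). The keyword lists were designed under the
#' platform's substring collection semantics, where `mask` also catches
#' "masks" and `test` catches "testing"; under the stricter token matching
#' used here the prevention keywords therefore take prefix form, which keeps
#' that coverage while still refusing accidental containments such as
#' "protest" for `test`.
#'
#' @return named list of `narrative_spec` objects.
#' @export
narrative_specs <- function() {
  list(
    HCQ = narrative_spec("HCQ", c("hcq", "hydroxychloroquine")),
    OFFICIALS = narrative_spec("OFFICIALS", c("fauci", "brix", "cdc")),
    PREVENTION = narrative_spec(
      "PREVENTION", c("mask*", "vaccine*", "social distanc*", "test*"))
  )
}

#' Define a narrative keyword filter
#'
#' @param name narrative label.
#' @param patterns character vector of lowercase keyword patterns; a pattern
#'   may span several tokens (matched consecutively) and a trailing `*`
#'   denotes token-prefix matching.
#' @return object of class `narrative_spec`.
#' @export
narrative_spec <- function(name, patterns) {
  patterns <- as.character(patterns)
  if (length(patterns) == 0 || any(!nzchar(patterns))) {
    abort("Narrative patterns must be non-empty.",
          class = "misinfo_config_error")
  }
  if (any(patterns != tolower(patterns))) {
    abort("Narrative patterns must be lowercase.",
          class = "misinfo_config_error")
  }
  compiled <- lapply(patterns, function(p) {
    toks <- strsplit(p, " +")[[1]]
    prefix <- grepl("\\*$", toks)
    list(tokens = sub("\\*$", "", toks), prefix = prefix)
  })
  structure(list(name = name, patterns = patterns, compiled = compiled),
            class = "narrative_spec")
}

match_pattern_tokens <- function(tokens, pat) {
  np <- length(pat$tokens)
  nt <- length(tokens)
  if (nt < np) return(FALSE)
  for (start in seq_len(nt - np + 1L)) {
    ok <- TRUE
    for (j in seq_len(np)) {
      tok <- tokens[start + j - 1L]
      want <- pat$tokens[j]
      hit <- if (pat$prefix[j]) startsWith(tok, want) else tok == want
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Tag tweets with narrative labels
#'
#' Matches each spec's keyword patterns against the case-folded, hash-sign
#' stripped token sequence of the text. Plain keywords match whole tokens,
#' `*`-suffixed patterns match token prefixes, and multi-word patterns must
#' match consecutive tokens; a tweet can carry several narrative tags. With
#' `substring = TRUE` matching falls back to raw case-insensitive substring
#' semantics (the behaviour of keyword tracking on the platform itself),
#' which is more permissive ("protest" then matches "test").
#'
#' @param text character vector of tweet texts.
#' @param specs list of [narrative_spec()]s (default [narrative_specs()]).
#' @param substring use substring matching instead of token matching.
#' @return list of character vectors: the matched narrative names per text.
#' @examples
#' tag_narratives("Fauci and the CDC lied about masks")
#' @export
tag_narratives <- function(text, specs = narrative_specs(),
                           substring = FALSE) {
  if (length(specs) == 0) {
    abort("`specs` must be non-empty.", class = "misinfo_config_error")
  }
  names_ <- vapply(specs, function(s) s$name, character(1))
  if (substring) {
    low <- tolower(text)
    return(lapply(low, function(tx) {
      hit <- vapply(specs, function(s) {
        any(vapply(s$patterns, function(p) {
          grepl(sub("\\*$", "", p), tx, fixed = TRUE)
        }, logical(1)))
      }, logical(1))
      names_[hit]
    }))
  }
  toks <- tokenize_text(text, drop_stopwords = FALSE)
  lapply(toks, function(tk) {
    hit <- vapply(specs, function(s) {
      any(vapply(s$compiled, function(p) match_pattern_tokens(tk, p),
                 logical(1)))
    }, logical(1))
    names_[hit]
  })
}

#' Top hashtags in a stream
#'
#' Counts hashtags case-insensitively; ties are broken lexicographically so
#' rankings are reproducible.
#'
#' @param tweets tweet tibble.
#' @param n number of hashtags to return.
#' @return tibble with columns `hashtag`, `count`, at most `n` rows.
#' @export
top_hashtags <- function(tweets, n) {
  if (n < 1) abort("`n` must be at least 1.", class = "misinfo_config_error")
  tags <- tolower(unlist(tweets$hashtags, use.names = FALSE))
  if (length(tags) == 0) {
    return(tibble(hashtag = character(), count = integer()))
  }
  tab <- table(tags)
  out <- tibble(hashtag = names(tab), count = as.integer(tab)) |>
    arrange(desc(.data$count), .data$hashtag)
  head(out, n)
}

# Trailing moving average; the first window-1 entries average the available
# prefix, so a constant series is a fixed point of the smoother.
trailing_mean <- function(x, window) {
  if (length(x) == 0) return(numeric())
  cs <- cumsum(x)
  n <- seq_along(x)
  lo <- pmax(n - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (n - lo)
}

#' Smoothed tweet-volume curve
#'
#' Bins tweets by UTC day or ISO week (weeks anchored on Monday), fills
#' missing bins with zero across the observed span, and applies a trailing
#' moving average of the given window (7 days and 7 weeks in the original
#' design). The first `window - 1` entries average over the available
#' prefix.
#'
#' @param tweets tweet tibble.
#' @param granularity `"day"` or `"week"`.
#' @param window moving-average window length, in bins.
#' @param label label stored in the output.
#' @return a `volume_series` tibble with columns `label`, `date`, `count`,
#'   `smoothed`.
#' @export
volume_curve <- function(tweets, granularity = c("day", "week"), window = 7,
                         label = "all") {
  granularity <- match.arg(granularity)
  if (window < 1) abort("`window` must be at least 1.",
                        class = "misinfo_config_error")
  if (nrow(tweets) == 0) {
    out <- tibble(label = character(), date = as.Date(character()),
                  count = integer(), smoothed = double())
    class(out) <- c("volume_series", class(out))
    return(out)
  }
  d <- lubridate::as_date(tweets$timestamp)
  if (granularity == "week") {
    d <- lubridate::floor_date(d, unit = "week", week_start = 1)
    step <- 7L
  } else {
    step <- 1L
  }
  span <- seq(min(d), max(d), by = step)
  counts <- as.integer(table(factor(as.character(d),
                                    levels = as.character(span))))
  out <- tibble(label = label, date = span, count = counts,
                smoothed = trailing_mean(counts, window))
  class(out) <- c("volume_series", class(out))
  out
}
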