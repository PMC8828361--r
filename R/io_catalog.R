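#' Reduce URLs to registered domains
#'
#' Normalizes each URL to its registered (public-suffix-aware) domain:
#' lowercases, strips scheme, credentials, port, path, query and fragment,
#' and collapses subdomains so `news.example.co.uk` becomes `example.co.uk`
#' and a leading `www.` never survives. Multi-label public suffixes are
#' resolved against a curated table of the country-code suffixes that occur
#' in news-domain catalogs (`co.uk`, `com.au`, `co.jp`, ...). Unparseable
#' input yields `NA` rather than an error, so a malformed URL in mid-stream
#' never aborts processing.
#'
#' @param url character vector of URLs or bare hostnames.
#' @return character vector of registered domains, `NA` where parsing fails.
#' @examples
#' url_to_domain("https://WWW.Example.com/a?b=1")       # "example.com"
#' url_to_domain("http://news.thegatewaypundit.com/x")  # "thegatewaypundit.com"
#' url_to_domain("not a url")                           # NA
#' @export
url_to_domain <- function(url) {
  host <- tolower(trimws(as.character(url)))
  host <- sub("^[a-z][a-z0-9+.-]*://", "", host)
  host <- sub("^[^/@]*@", "", host)           # credentials
  host <- sub("[/?#].*$", "", host)           # path / query / fragment
  host <- sub(":[0-9]*$", "", host)           # port
  host <- sub("\\.$", "", host)               # trailing dot
  bad <- is.na(host) | !grepl("^[a-z0-9][a-z0-9.-]*\\.[a-z][a-z0-9-]*$", host)
  host[bad] <- NA_character_
  vapply(host, registered_domain, character(1), USE.NAMES = FALSE)
}

# Multi-label public suffixes relevant to news domains; a curated subset of
# the public-suffix list (single-label TLDs need no table).
multi_label_suffixes <- c(
  "co.uk", "org.uk", "ac.uk", "gov.uk", "me.uk", "net.uk",
  "co.jp", "ne.jp", "or.jp", "go.jp", "ac.jp",
  "com.au", "net.au", "org.au", "gov.au", "edu.au",
  "com.br", "org.br", "gov.br", "net.br",
  "co.in", "org.in", "gov.in", "net.in", "ac.in",
  "co.nz", "org.nz", "govt.nz", "net.nz",
  "co.za", "org.za", "gov.za",
  "com.mx", "org.mx", "gob.mx",
  "com.cn", "org.cn", "gov.cn", "net.cn",
  "com.ar", "org.ar", "gov.ar",
  "com.tr", "org.tr", "gov.tr",
  "co.kr", "or.kr", "go.kr",
  "com.sg", "org.sg", "gov.sg",
  "com.hk", "org.hk", "gov.hk",
  "co.id", "or.id", "go.id",
  "com.my", "org.my", "gov.my",
  "com.tw", "org.tw", "gov.tw",
  "co.th", "or.th", "go.th",
  "com.ua", "gov.ua", "com.pk", "gov.pk",
  "com.eg", "gov.eg", "com.sa", "gov.sa",
  "com.ng", "gov.ng", "co.ke", "go.ke",
  "com.ph", "gov.ph", "com.vn", "gov.vn",
  "co.il", "org.il", "gov.il",
  "com.co", "gov.co", "com.pe", "gob.pe",
  "com.cl", "gob.cl", "com.ec", "gob.ec",
  "com.ve", "gob.ve", "com.uy", "gub.uy"
)

registered_domain <- function(host) {
  if (is.na(host)) return(NA_character_)
  labels <- strsplit(host, ".", fixed = TRUE)[[1]]
  n <- length(labels)
  if (n < 2) return(NA_character_)
  last2 <- paste(labels[n - 1L], labels[n], sep = ".")
  if (n >= 3 && last2 %in% multi_label_suffixes) {
    paste(labels[n - 2L], last2, sep = ".")
  } else {
    last2
  }
}

tweet_stream_prototype <- function() {
  tibble(
    tweet_id = character(), user_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    text = character(), lang = character(),
    urls = list(), hashtags = list(),
    retweeted_user_id = character(), retweeted_tweet_id = character()
  )
}

# Structural validation only; timestamp strings are parsed in one vectorized
# pass afterwards.
validate_tweet_line <- function(rec) {
  if (!is.list(rec)) return(NULL)
  need <- c("tweet_id", "user_id", "timestamp", "text")
  for (f in need) {
    v <- rec[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v)) return(NULL)
  }
  rt_u <- rec$retweeted_user_id
  rt_t <- rec$retweeted_tweet_id
  if (is.null(rt_u) != is.null(rt_t)) return(NULL)  # both or neither
  list(
    tweet_id = as.character(rec$tweet_id),
    user_id = as.character(rec$user_id),
    timestamp = as.character(rec$timestamp),
    text = as.character(rec$text),
    lang = if (is.null(rec$lang)) "und" else as.character(rec$lang),
    urls = as.character(unlist(rec$urls)),
    hashtags = tolower(as.character(unlist(rec$hashtags))),
    retweeted_user_id = if (is.null(rt_u)) NA_character_ else as.character(rt_u),
    retweeted_tweet_id = if (is.null(rt_t)) NA_character_ else as.character(rt_t)
  )
}

#' Read a JSON-lines tweet stream
#'
#' One JSON object per line with fields `tweet_id`, `user_id`, `timestamp`
#' (ISO-8601, UTC), `text`, `lang`, `urls`, `hashtags`,
#' `retweeted_user_id`/`retweeted_tweet_id` (both present or both absent).
#' Malformed lines are skipped with a warning and counted in the
#' `skipped_lines` attribute of the result; more than half malformed is
#' treated as a format error.
#'
#' @param path path to a JSONL file.
#' @return tweet tibble (see [generate_stream()] for the schema) with
#'   attribute `skipped_lines`.
#' @export
read_tweets <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read tweet stream: '%s' does not exist.", path),
          class = "misinfo_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tweet_stream_prototype()
    attr(out, "skipped_lines") <- 0L
    return(out)
  }
  # fast path: parse the whole file as one JSON array; fall back to
  # line-by-line parsing (so malformed lines can be counted and skipped)
  # only when that fails
  raw <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                       simplifyVector = FALSE),
    error = function(e) NULL)
  if (is.null(raw)) {
    raw <- lapply(lines, function(ln) {
      tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
               error = function(e) NULL)
    })
  }
  parsed <- lapply(raw, validate_tweet_line)
  ok <- !vapply(parsed, is.null, logical(1))
  # timestamps validated in one vectorized pass
  if (any(ok)) {
    ts_chr <- vapply(parsed[ok], function(r) r$timestamp, character(1))
    ts <- lubridate::ymd_hms(ts_chr, tz = "UTC", quiet = TRUE)
    bad_ts <- which(ok)[is.na(ts)]
    ok[bad_ts] <- FALSE
    ts <- ts[!is.na(ts)]
  } else {
    ts <- as.POSIXct(character(), tz = "UTC")
  }
  n_skip <- sum(!ok)
  if (n_skip > length(lines) / 2) {
    abort(sprintf(
      "More than half of '%s' is malformed (%d of %d lines); not a tweet JSONL file.",
      path, n_skip, length(lines)), class = "misinfo_format_error")
  }
  if (n_skip > 0) {
    warn(sprintf("Skipped %d malformed line(s) while reading '%s'.",
                 n_skip, path))
  }
  recs <- parsed[ok]
  out <- tibble(
    tweet_id = map_chr(recs, "tweet_id"),
    user_id = map_chr(recs, "user_id"),
    timestamp = ts,
    text = map_chr(recs, "text"),
    lang = map_chr(recs, "lang"),
    urls = map(recs, "urls"),
    hashtags = map(recs, "hashtags"),
    retweeted_user_id = map_chr(recs, "retweeted_user_id"),
    retweeted_tweet_id = map_chr(recs, "retweeted_tweet_id")
  )
  attr(out, "skipped_lines") <- n_skip
  out
}

#' Write a tweet stream as JSON lines
#'
#' Inverse of [read_tweets()]; timestamps are written as ISO-8601 UTC with
#' microsecond precision, and the retweet fields are omitted for original
#' tweets.
#'
#' @param tweets tweet tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  df <- data.frame(
    tweet_id = tweets$tweet_id,
    user_id = tweets$user_id,
    timestamp = format(tweets$timestamp, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC"),
    text = tweets$text,
    lang = tweets$lang,
    retweeted_user_id = tweets$retweeted_user_id,
    retweeted_tweet_id = tweets$retweeted_tweet_id,
    stringsAsFactors = FALSE
  )
  df$urls <- lapply(tweets$urls, as.character)
  df$hashtags <- lapply(tweets$hashtags, as.character)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, na = "null",
                       auto_unbox = TRUE, always_decimal = FALSE)
  invisible(path)
}

reliability_vocab <- c("conspiracy", "questionable", "reliable", "unknown")
bias_vocab <- c("left", "left_center", "least", "right_center", "right",
                "unknown")

#' Load a credibility/bias domain catalog
#'
#' Reads a CSV with header `domain,reliability,bias`, normalizes domains via
#' the [url_to_domain()] rules, validates the closed label vocabularies
#' (reliability: conspiracy, questionable, reliable, unknown; bias: left,
#' left_center, least, right_center, right, unknown) and resolves duplicate
#' domains last-wins with a warning.
#'
#' @param path path to the catalog CSV.
#' @return tibble with columns `domain`, `reliability`, `bias`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read catalog: '%s' does not exist.", path),
          class = "misinfo_io_error")
  }
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("domain", "reliability", "bias")
  if (!all(need %in% names(raw))) {
    abort("Catalog must have columns domain,reliability,bias.",
          class = "misinfo_format_error")
  }
  bad_rel <- which(!(raw$reliability %in% reliability_vocab))
  if (length(bad_rel) > 0) {
    abort(sprintf("Row %d of '%s': unknown reliability value '%s'.",
                  bad_rel[1], path, raw$reliability[bad_rel[1]]),
          class = "misinfo_format_error")
  }
  bad_bias <- which(!(raw$bias %in% bias_vocab))
  if (length(bad_bias) > 0) {
    abort(sprintf("Row %d of '%s': unknown bias value '%s'.",
                  bad_bias[1], path, raw$bias[bad_bias[1]]),
          class = "misinfo_format_error")
  }
  dom <- url_to_domain(raw$domain)
  bad_dom <- which(is.na(dom))
  if (length(bad_dom) > 0) {
    abort(sprintf("Row %d of '%s': unparseable domain '%s'.",
                  bad_dom[1], path, raw$domain[bad_dom[1]]),
          class = "misinfo_format_error")
  }
  if (anyDuplicated(dom)) {
    warn(sprintf("Catalog '%s' has %d duplicate domain(s); keeping the last occurrence.",
                 path, sum(duplicated(dom))))
  }
  keep <- !duplicated(dom, fromLast = TRUE)   # last wins
  tibble(domain = dom[keep],
         reliability = raw$reliability[keep],
         bias = raw$bias[keep])
}

#' Write a domain catalog CSV
#'
#' @param catalog tibble with columns `domain`, `reliability`, `bias`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.csv(catalog[, c("domain", "reliability", "bias")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a source group
#'
#' A named set of domains used for group-level counting and co-sharing
#' analysis; the three study groups (conspiracy, questionable, random) are
#' conventionally built at the same cardinality (250 in the original design).
#'
#' @param name group name, one of `"conspiracy"`, `"questionable"`,
#'   `"random"`.
#' @param domains character vector of registered domains.
#' @return object of class `source_group`.
#' @export
source_group <- function(name, domains) {
  name <- match.arg(name, c("conspiracy", "questionable", "random"))
  structure(list(name = name, domains = sort(unique(as.character(domains)))),
            class = "source_group")
}

#' @export
print.source_group <- function(x, ...) {
  cat(sprintf("<source_group '%s': %d domains>\n", x$name, length(x$domains)))
  invisible(x)
}

#' Registered domains shared anywhere in a tweet stream
#'
#' @param tweets tweet tibble.
#' @return sorted character vector of unique registered domains.
#' @export
shared_domains <- function(tweets) {
  urls <- unlist(tweets$urls, use.names = FALSE)
  if (length(urls) == 0) return(character())
  sort(unique(stats::na.omit(url_to_domain(urls))))
}

#' Sample the random baseline source group
#'
#' Draws a uniform sample without replacement from the domains observed in
#' the data, excluding the unreliable lists so the baseline is disjoint from
#' the groups it is compared against. Deterministic for a fixed seed. The
#' caller passes the same `k` as the unreliable groups (250 in the original
#' design) so all three groups have equal cardinality.
#'
#' @param all_shared_domains character vector of candidate domains (typically
#'   [shared_domains()] of the stream).
#' @param exclude domains to exclude (the conspiracy and questionable lists).
#' @param k sample size.
#' @param seed RNG seed.
#' @return a `"random"` [source_group()].
#' @export
sample_random_sources <- function(all_shared_domains, exclude = character(),
                                  k, seed = 1L) {
  candidates <- sort(setdiff(unique(all_shared_domains), exclude))
  if (k < 0) abort("`k` must be nonnegative.", class = "misinfo_config_error")
  if (length(candidates) < k) {
    abort(sprintf(
      "Need %d candidate domains for the random baseline but only %d remain after exclusion.",
      k, length(candidates)), class = "misinfo_config_error")
  }
  picked <- if (k == 0) character() else {
    withr::with_seed(seed, sample(candidates, k))
  }
  source_group("random", picked)
}

#' Unreliable source groups from a catalog
#'
#' Builds the conspiracy and questionable [source_group()]s from a catalog,
#' optionally downsampling each to a common size `k`.
#'
#' @param catalog catalog tibble from [load_catalog()].
#' @param k optional group size; `NULL` keeps every listed domain.
#' @param seed RNG seed used only when downsampling.
#' @return named list with elements `conspiracy` and `questionable`.
#' @export
unreliable_groups <- function(catalog, k = NULL, seed = 1L) {
  pick <- function(rel) {
    doms <- sort(catalog$domain[catalog$reliability == rel])
    if (!is.null(k)) {
      if (length(doms) < k) {
        abort(sprintf("Catalog has only %d %s domains but k=%d requested.",
                      length(doms), rel, k), class = "misinfo_config_error")
      }
      doms <- withr::with_seed(seed, sample(doms, k))
    }
    source_group(if (rel == "conspiracy") "conspiracy" else "questionable",
                 doms)
  }
  list(conspiracy = pick("conspiracy"), questionable = pick("questionable"))
}
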