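#' Weekly normalized bigram time series
#'
#' Tokenizes tweets (lowercasing, stripping hash signs, dropping stop words
#' and punctuation), forms consecutive token pairs, keeps the `top_n` most
#' frequent bigrams overall (ties broken lexicographically so the selection
#' is deterministic), and builds for each one a weekly series of
#' `count / total bigram tokens that week`. Weekly totals count all bigrams
#' used that week, before top-n selection.
#'
#' @param tweets tweet tibble.
#' @param top_n number of bigrams to retain (50,000 in the original design;
#'   far fewer at desk scale).
#' @return object of class `bigram_series`: a list with `bigrams`
#'   (character), `weeks` (Date, Monday-anchored), `counts` and `freq`
#'   (bigram x week matrices), and `weekly_totals`.
#' @export
extract_bigrams <- function(tweets, top_n) {
  if (top_n < 1) abort("`top_n` must be at least 1.",
                       class = "misinfo_config_error")
  empty <- structure(list(bigrams = character(),
                          weeks = as.Date(character()),
                          counts = matrix(0, 0, 0), freq = matrix(0, 0, 0),
                          weekly_totals = integer()),
                     class = "bigram_series")
  if (nrow(tweets) == 0) return(empty)
  toks <- tokenize_text(tweets$text, drop_stopwords = TRUE)
  week <- lubridate::floor_date(lubridate::as_date(tweets$timestamp),
                                unit = "week", week_start = 1)
  grams <- map(toks, function(tk) {
    if (length(tk) < 2) return(character())
    paste(tk[-length(tk)], tk[-1])
  })
  n_per <- lengths(grams)
  if (sum(n_per) == 0) return(empty)
  df <- tibble(bigram = unlist(grams, use.names = FALSE),
               week = rep(week, n_per))
  weeks <- seq(min(df$week), max(df$week), by = 7L)
  totals <- as.integer(table(factor(as.character(df$week),
                                    levels = as.character(weeks))))
  freq_all <- count(df, .data$bigram, name = "total") |>
    arrange(desc(.data$total), .data$bigram)
  keep <- head(freq_all$bigram, top_n)
  dfk <- df[df$bigram %in% keep, ]
  counts <- table(factor(dfk$bigram, levels = keep),
                  factor(as.character(dfk$week),
                         levels = as.character(weeks)))
  counts <- matrix(as.integer(counts), nrow = length(keep),
                   dimnames = list(keep, as.character(weeks)))
  freq <- sweep(counts, 2, pmax(totals, 1L), "/")
  structure(list(bigrams = keep, weeks = weeks, counts = counts,
                 freq = freq, weekly_totals = totals),
            class = "bigram_series")
}

#' @export
print.bigram_series <- function(x, ...) {
  cat(sprintf("<bigram_series: %d bigrams x %d weeks (%s to %s)>\n",
              length(x$bigrams), length(x$weeks),
              if (length(x$weeks)) format(min(x$weeks)) else "-",
              if (length(x$weeks)) format(max(x$weeks)) else "-"))
  invisible(x)
}

# Largest share of a series' total mass inside any contiguous window of
# `w` bins; scale-invariant by construction.
best_window_fraction <- function(x, w) {
  tot <- sum(x)
  if (tot <= 0) return(0)
  w <- min(w, length(x))
  cs <- cumsum(x)
  wins <- cs[w:length(x)] - c(0, cs)[1:(length(x) - w + 1L)]
  max(wins) / tot
}

#' Cluster bigram series by temporal shape
#'
#' A reproducible stand-in for shape-based time-series clustering of bursty
#' social media n-grams. Three steps: (1) a burst filter drops bigrams whose
#' best contiguous window of `window_days` holds less than `burst_fraction`
#' of their total normalized mass, removing perennially trending phrases
#' that would otherwise dominate every cluster; (2) surviving series are
#' z-normalized so only shape, not scale, matters; (3) k-means on the
#' z-normalized rows (squared Euclidean distance on z-scored series is a
#' monotone transform of one minus the Pearson correlation, so this is
#' correlation-distance clustering) with seeded initialization. Series are
#' sorted by bigram before clustering so memberships are invariant to input
#' order, and clusters are reported ordered by peak week.
#'
#' @param series a `bigram_series` from [extract_bigrams()].
#' @param k number of clusters (11 in the original design).
#' @param window_days burst window length in days; rounded to whole weeks
#'   (21 days, i.e. 3 weeks, in the original design).
#' @param burst_fraction minimum share of a bigram's mass that must fall in
#'   its best window (default 0.5, a majority-of-mass rule).
#' @param seed RNG seed for the k-means initialization.
#' @return tibble of class `temporal_clusters` with columns `cluster_id`,
#'   `n_members`, `peak_week`, `members` (list); attributes `shapes` (mean
#'   normalized series per cluster) and `filtered` (bigrams dropped by the
#'   burst filter).
#' @export
shape_cluster <- function(series, k, window_days = 21, burst_fraction = 0.5,
                          seed = 1L) {
  stopifnot(inherits(series, "bigram_series"))
  if (k < 1) abort("`k` must be at least 1.", class = "misinfo_config_error")
  if (window_days < 7) abort("`window_days` must be at least 7.",
                             class = "misinfo_config_error")
  if (length(series$bigrams) == 0) {
    abort("No bigram series to cluster.", class = "misinfo_config_error")
  }
  w_weeks <- max(1L, as.integer(round(window_days / 7)))
  ord <- order(series$bigrams)
  freq <- series$freq[ord, , drop = FALSE]

  frac <- apply(freq, 1, best_window_fraction, w = w_weeks)
  sds <- apply(freq, 1, sd)
  survivors <- frac >= burst_fraction & sds > 0
  filtered <- rownames(freq)[!survivors]
  fs <- freq[survivors, , drop = FALSE]
  if (nrow(fs) < k) {
    abort(sprintf(
      "k = %d exceeds the %d bigrams surviving the burst filter (of %d).",
      k, nrow(fs), nrow(freq)), class = "misinfo_config_error")
  }
  z <- t(scale(t(fs)))
  km <- withr::with_seed(seed,
                         kmeans(z, centers = k, iter.max = 200, nstart = 10))

  shapes <- t(vapply(seq_len(k), function(ci) {
    colMeans(fs[km$cluster == ci, , drop = FALSE])
  }, double(ncol(fs))))
  peak_idx <- apply(shapes, 1, which.max)
  peak_order <- order(series$weeks[peak_idx],
                      vapply(seq_len(k), function(ci) {
                        min(rownames(fs)[km$cluster == ci])
                      }, character(1)))
  out <- tibble(
    cluster_id = seq_len(k),
    n_members = as.integer(table(factor(km$cluster,
                                        levels = peak_order))),
    peak_week = series$weeks[peak_idx[peak_order]],
    members = lapply(peak_order, function(ci) {
      sort(rownames(fs)[km$cluster == ci])
    })
  )
  attr(out, "shapes") <- shapes[peak_order, , drop = FALSE]
  attr(out, "filtered") <- filtered
  class(out) <- c("temporal_clusters", class(out))
  out
}

# ---- latent topic model (collapsed-Gibbs LDA) -------------------------------

lda_gibbs <- function(docs_idx, n_vocab, k, alpha = NULL, beta = 0.1,
                      iters = 120) {
  if (is.null(alpha)) alpha <- 50 / k
  doc_id <- rep.int(seq_along(docs_idx), lengths(docs_idx))
  word <- unlist(docs_idx, use.names = FALSE)
  n_tok <- length(word)
  n_doc <- length(docs_idx)
  z <- sample.int(k, n_tok, replace = TRUE)
  cdt <- matrix(0L, n_doc, k)   # doc-topic counts
  cwt <- matrix(0L, n_vocab, k) # word-topic counts
  ct <- integer(k)
  for (i in seq_len(n_tok)) {
    cdt[doc_id[i], z[i]] <- cdt[doc_id[i], z[i]] + 1L
    cwt[word[i], z[i]] <- cwt[word[i], z[i]] + 1L
    ct[z[i]] <- ct[z[i]] + 1L
  }
  for (it in seq_len(iters)) {
    u <- runif(n_tok)
    for (i in seq_len(n_tok)) {
      ti <- z[i]; di <- doc_id[i]; wi <- word[i]
      cdt[di, ti] <- cdt[di, ti] - 1L
      cwt[wi, ti] <- cwt[wi, ti] - 1L
      ct[ti] <- ct[ti] - 1L
      p <- (cdt[di, ] + alpha) * (cwt[wi, ] + beta) / (ct + n_vocab * beta)
      ti <- findInterval(u[i] * sum(p), cumsum(p)) + 1L
      z[i] <- ti
      cdt[di, ti] <- cdt[di, ti] + 1L
      cwt[wi, ti] <- cwt[wi, ti] + 1L
      ct[ti] <- ct[ti] + 1L
    }
  }
  list(cwt = cwt, cdt = cdt)
}

# UMass coherence of one topic's top terms from document co-occurrence.
umass_coherence <- function(top_idx, doc_sets) {
  df <- vapply(top_idx, function(w) {
    sum(vapply(doc_sets, function(s) w %in% s, logical(1)))
  }, double(1))
  total <- 0; n_pairs <- 0
  for (a in 2:length(top_idx)) {
    for (b in 1:(a - 1)) {
      co <- sum(vapply(doc_sets, function(s) {
        top_idx[a] %in% s && top_idx[b] %in% s
      }, logical(1)))
      total <- total + log((co + 1) / max(df[b], 1))
      n_pairs <- n_pairs + 1
    }
  }
  total / n_pairs
}

#' Coherence-selected latent topic model
#'
#' Fits a latent Dirichlet allocation topic model (collapsed Gibbs sampling)
#' for each candidate number of topics, scores each fit by the mean UMass
#' coherence of its topics' top terms, and returns the candidate with the
#' largest coherence (4 topics in the original analysis). Seeded and
#' repeatable: the same call with the same seed returns identical topic-term
#' rankings.
#'
#' @param tweets tweet tibble (at least 50 documents after preprocessing).
#' @param n_candidates integer vector of candidate topic counts.
#' @param seed RNG seed.
#' @param n_top_terms number of top terms per topic used for reporting and
#'   coherence (default 10).
#' @param iters Gibbs sweeps per fit (default 120).
#' @return list with `chosen_n`, `topics` (list of character vectors of top
#'   terms, for the chosen fit), and `coherence` (named by candidate).
#' @export
topic_model <- function(tweets, n_candidates, seed = 1L, n_top_terms = 10,
                        iters = 120) {
  toks <- tokenize_text(tweets$text, drop_stopwords = TRUE)
  toks <- toks[lengths(toks) > 0]
  if (length(toks) < 50) {
    abort("Topic modeling needs at least 50 non-empty documents.",
          class = "misinfo_config_error")
  }
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (length(vocab) == 0) {
    abort("Empty vocabulary after preprocessing.",
          class = "misinfo_config_error")
  }
  docs_idx <- lapply(toks, function(tk) match(tk, vocab))
  doc_sets <- lapply(docs_idx, unique)

  fit_one <- function(k) {
    fit <- lda_gibbs(docs_idx, length(vocab), k, iters = iters)
    topics <- lapply(seq_len(k), function(ti) {
      o <- order(-fit$cwt[, ti], vocab)
      vocab[head(o, n_top_terms)]
    })
    coh <- if (k == 1) {
      umass_coherence(match(topics[[1]], vocab), doc_sets)
    } else {
      mean(vapply(topics, function(tt) {
        umass_coherence(match(tt, vocab), doc_sets)
      }, double(1)))
    }
    list(topics = topics, coherence = coh)
  }

  fits <- withr::with_seed(seed, lapply(n_candidates, fit_one))
  coh <- vapply(fits, function(f) f$coherence, double(1))
  names(coh) <- as.character(n_candidates)
  best <- which.max(coh)
  list(chosen_n = n_candidates[best],
       topics = fits[[best]]$topics,
       coherence = coh)
}
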