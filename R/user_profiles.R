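bias_classes <- c("left", "left_center", "least", "right_center", "right")

#' Profile users' political lean and misinformation engagement
#'
#' Tallies, per user, the URLs they shared (originals and retweets both
#' republish a URL), resolves each to its registered domain, and looks the
#' domain up in the catalog. A user's lean is the political bias class with
#' the most shared domains; exact ties are broken uniformly at random among
#' the tied classes under the given seed. Users with at most `min_urls`
#' shared URLs ("more than five" read strictly) or no bias-bearing shares
#' are left `unclassified`. Any user who shared at least one conspiracy or
#' questionable domain is flagged `misinfo_engaged`, regardless of the URL
#' filter. If narrative specs are supplied, each user carries the union of
#' narrative tags over their tweets.
#'
#' @param tweets tweet tibble (conventionally the misinformation subset when
#'   narrative tags are wanted).
#' @param catalog catalog tibble from [load_catalog()].
#' @param min_urls classification threshold: users need strictly more than
#'   this many shared URLs (default 5).
#' @param seed RNG seed for tie-breaking.
#' @param count_uncataloged if `TRUE` (default) URLs resolving to domains
#'   absent from the catalog still count toward `n_urls` (the URL filter
#'   speaks of shared URLs, not cataloged ones); they never contribute to
#'   bias counts either way.
#' @param specs optional list of [narrative_spec()]s for narrative tagging;
#'   `NULL` skips tagging.
#' @return tibble with columns `user_id`, `n_urls`, one count column per
#'   bias class (`left`, `left_center`, `least`, `right_center`, `right`),
#'   `lean`, `misinfo_engaged`, `narratives` (pipe-separated tags, `""` when
#'   untagged or `specs` is `NULL`).
#' @export
build_profiles <- function(tweets, catalog, min_urls = 5, seed = 1L,
                           count_uncataloged = TRUE, specs = NULL) {
  users <- sort(unique(tweets$user_id))
  n_url_tw <- lengths(tweets$urls)
  url_df <- tibble(
    user_id = rep(tweets$user_id, n_url_tw),
    domain = url_to_domain(unlist(tweets$urls, use.names = FALSE))
  )
  url_df <- url_df[!is.na(url_df$domain), ]
  url_df <- left_join(url_df, catalog, by = "domain")

  counted <- if (count_uncataloged) url_df else
    url_df[!is.na(url_df$reliability), ]
  n_urls <- count(counted, .data$user_id, name = "n_urls")

  bias_tab <- url_df |>
    filter(.data$bias %in% bias_classes) |>
    count(.data$user_id, .data$bias) |>
    pivot_wider(names_from = "bias", values_from = "n", values_fill = 0L)
  for (b in bias_classes) {
    if (!b %in% names(bias_tab)) bias_tab[[b]] <- 0L
  }

  engaged <- url_df |>
    filter(.data$reliability %in% c("conspiracy", "questionable")) |>
    distinct(.data$user_id) |>
    mutate(misinfo_engaged = TRUE)

  prof <- tibble(user_id = users) |>
    left_join(n_urls, by = "user_id") |>
    left_join(bias_tab, by = "user_id") |>
    left_join(engaged, by = "user_id") |>
    mutate(
      n_urls = coalesce(.data$n_urls, 0L),
      across(all_of(bias_classes), ~ coalesce(.x, 0L)),
      misinfo_engaged = coalesce(.data$misinfo_engaged, FALSE)
    )

  counts_mat <- as.matrix(prof[, bias_classes])
  lean <- withr::with_seed(seed, {
    apply_lean(counts_mat, prof$n_urls, min_urls)
  })
  prof$lean <- lean

  prof$narratives <- ""
  if (!is.null(specs)) {
    tags <- tag_narratives(tweets$text, specs)
    tag_df <- tibble(user_id = rep(tweets$user_id, lengths(tags)),
                     tag = unlist(tags, use.names = FALSE))
    if (nrow(tag_df) > 0) {
      per_user <- tag_df |>
        distinct(.data$user_id, .data$tag) |>
        arrange(.data$user_id, .data$tag) |>
        summarise(narratives = paste(.data$tag, collapse = "|"),
                  .by = "user_id")
      idx <- match(prof$user_id, per_user$user_id)
      prof$narratives <- ifelse(is.na(idx), "", per_user$narratives[idx])
    }
  }
  prof[, c("user_id", "n_urls", bias_classes, "lean", "misinfo_engaged",
           "narratives")]
}

# Majority lean per row; exact ties drawn uniformly among the tied classes
# (draws are consumed only for tied rows, in row order).
apply_lean <- function(counts_mat, n_urls, min_urls) {
  lean <- rep("unclassified", nrow(counts_mat))
  for (i in seq_len(nrow(counts_mat))) {
    if (n_urls[i] <= min_urls) next
    cm <- counts_mat[i, ]
    m <- max(cm)
    if (m == 0) next
    tied <- bias_classes[cm == m]
    lean[i] <- if (length(tied) == 1) tied else tied[sample.int(length(tied), 1)]
  }
  lean
}

#' Compare assigned leans against generator ground truth
#'
#' Joins profiles with the [truth_table()] of the stream they were built
#' from and reports confusion counts of assigned lean against latent lean
#' among classified users, collapsing assigned `left`/`left_center` to the
#' latent `left` side and `right`/`right_center` to `right` (`least` matches
#' neither side).
#'
#' @param profiles tibble from [build_profiles()].
#' @param truth tibble from [truth_table()].
#' @return list with `confusion` (tibble latent_lean x assigned side),
#'   `accuracy_by_lean`, `overall_accuracy`, and `n_classified`.
#' @export
lean_recovery_report <- function(profiles, truth) {
  if (!all(profiles$user_id %in% truth$user_id)) {
    abort("Profiles contain user ids absent from the truth table.",
          class = "misinfo_config_error")
  }
  joined <- inner_join(profiles, truth, by = "user_id") |>
    filter(.data$lean != "unclassified")
  side <- dplyr::case_when(
    joined$lean %in% c("left", "left_center") ~ "left",
    joined$lean %in% c("right", "right_center") ~ "right",
    TRUE ~ "least"
  )
  joined$assigned_side <- side
  joined$correct <- side == joined$latent_lean
  confusion <- count(joined, .data$latent_lean, .data$assigned_side)
  by_lean <- summarise(joined, accuracy = mean(.data$correct),
                       n = dplyr::n(), .by = "latent_lean")
  list(confusion = confusion,
       accuracy_by_lean = by_lean,
       overall_accuracy = mean(joined$correct),
       n_classified = nrow(joined))
}

#' Write user profiles as CSV
#'
#' @param profiles tibble from [build_profiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}
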