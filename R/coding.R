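# Inclusion/exclusion funnel and 47-dimensional binary coding of posts.

#' Filter-funnel report
#'
#' Counts at each stage of the selection funnel: posts in, posts on the
#' cancer topic carrying at least one emotion term (after stop-keyword
#' removal), posts excluded for advertising keywords, and posts selected.
#' The identity `n_selected = n_with_emotion - n_ad_excluded` always
#' holds.
#'
#' @param n_input number of posts considered.
#' @param n_with_emotion posts on topic with at least one emotion term.
#' @param n_ad_excluded of those, posts excluded for advertising keywords.
#' @param n_cancer_topic optional: posts passing the topic + stop filter.
#' @param n_stop_excluded optional: topical posts dropped by stop keywords.
#' @return object of class `filter_report`.
#' @examples
#' filter_report(1854497, 434299, 112960)$n_selected  # 321339
#' @export
filter_report <- function(n_input, n_with_emotion, n_ad_excluded,
                          n_cancer_topic = NA_integer_,
                          n_stop_excluded = NA_integer_) {
  if (n_with_emotion > n_input) {
    stop("n_with_emotion cannot exceed n_input")
  }
  if (n_ad_excluded > n_with_emotion) {
    stop("n_ad_excluded cannot exceed n_with_emotion")
  }
  structure(
    list(n_input = as.integer(n_input),
         n_cancer_topic = as.integer(n_cancer_topic),
         n_stop_excluded = as.integer(n_stop_excluded),
         n_with_emotion = as.integer(n_with_emotion),
         n_ad_excluded = as.integer(n_ad_excluded),
         n_selected = as.integer(n_with_emotion - n_ad_excluded)),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Selection funnel\n")
  cat(sprintf("  input posts:        %d\n", x$n_input))
  if (!is.na(x$n_cancer_topic)) {
    cat(sprintf("  on cancer topic:    %d (stop-keyword posts removed: %d)\n",
                x$n_cancer_topic, x$n_stop_excluded))
  }
  cat(sprintf("  with emotion terms: %d\n", x$n_with_emotion))
  cat(sprintf("  ad-keyword posts:   -%d\n", x$n_ad_excluded))
  cat(sprintf("  selected:           %d\n", x$n_selected))
  invisible(x)
}

# Bulk item/role matching for a posts data.frame; returns list of two
# logical matrices.
match_posts <- function(posts, lexicon) {
  texts <- post_match_strings(posts$text)
  catalog <- lexicon$catalog
  all_targets <- c(catalog$all_items, catalog$role_markers)
  hits <- match_term_matrix(texts, lexicon, all_targets)
  list(items = hits[, catalog$all_items, drop = FALSE],
       roles = hits[, catalog$role_markers, drop = FALSE])
}

#' Apply the selection funnel to posts
#'
#' A post is kept iff it (a) mentions the cancer topic (a generic cancer
#' keyword or any cancer-type item), (b) mentions at least one emotion
#' term, (c) matches no stop keyword, and (d) matches no advertising
#' keyword. Stop-keyword posts are removed before the emotion count;
#' advertising posts are subtracted after it, so the funnel identity
#' `n_selected = n_with_emotion - n_ad_excluded` holds.
#'
#' @param posts data.frame with columns `id`, `channel`, `text`.
#' @param lexicon an `emo_lexicon`.
#' @return list with `posts` (the kept rows, carrying a precomputed match
#'   matrix used by [code_posts()]) and `report` (a [filter_report()]).
#' @export
filter_posts <- function(posts, lexicon) {
  stopifnot(all(c("id", "channel", "text") %in% names(posts)))
  n <- nrow(posts)
  if (n == 0) {
    kept <- posts[0, , drop = FALSE]
    attr(kept, "item_matrix") <-
      matrix(FALSE, 0, length(lexicon$catalog$all_items),
             dimnames = list(NULL, lexicon$catalog$all_items))
    return(list(posts = kept, report = filter_report(0, 0, 0, 0, 0)))
  }
  mm <- match_posts(posts, lexicon)
  catalog <- lexicon$catalog
  cancer_cols <- names(catalog$factor_category)[
    catalog$factor_category == "cancer_type"]
  has_cancer <- mm$roles[, "cancer_keyword"] |
    rowSums(mm$items[, cancer_cols, drop = FALSE]) > 0
  has_stop <- mm$roles[, "stop_keyword"]
  on_topic <- has_cancer & !has_stop
  has_emotion <- rowSums(mm$items[, catalog$emotion_groups,
                                  drop = FALSE]) > 0
  with_emotion <- on_topic & has_emotion
  is_ad <- mm$roles[, "ad_keyword"]
  selected <- with_emotion & !is_ad

  report <- filter_report(
    n_input = n,
    n_with_emotion = sum(with_emotion),
    n_ad_excluded = sum(with_emotion & is_ad),
    n_cancer_topic = sum(on_topic),
    n_stop_excluded = sum(has_cancer & has_stop)
  )
  kept <- posts[selected, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "item_matrix") <- mm$items[selected, , drop = FALSE]
  list(posts = kept, report = report)
}

#' Transaction set: posts as binary item vectors
#'
#' @param mat 0/1 or logical matrix, one row per post, columns named by
#'   item.
#' @param post_id character vector of post ids.
#' @param channel character vector of channels.
#' @param items optional item universe (defaults to `colnames(mat)`).
#' @return object of class `transaction_set`: list with `items`,
#'   `post_id`, `channel`, `matrix` (integer 0/1), `n_posts`.
#' @export
transaction_set <- function(mat, post_id = NULL, channel = NULL,
                            items = colnames(mat)) {
  mat <- as.matrix(mat) * 1L
  if (is.null(items)) stop("item names are required")
  colnames(mat) <- items
  n <- nrow(mat)
  if (is.null(post_id)) post_id <- sprintf("post_%05d", seq_len(n))
  if (is.null(channel)) channel <- "blog"
  if (length(channel) == 1) channel <- rep(channel, n)
  if (length(post_id) != n || length(channel) != n) {
    stop("post_id and channel must have one entry per row")
  }
  structure(list(items = items, post_id = post_id,
                 channel = as.character(channel),
                 matrix = mat, n_posts = n),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("Transaction set: %d posts x %d items (density %.3f)\n",
              x$n_posts, length(x$items),
              if (x$n_posts > 0) mean(x$matrix) else 0))
  invisible(x)
}

#' Code filtered posts into 47-item binary transactions
#'
#' Sets `indicator[item] = 1` iff the lexicon matcher found the item in
#' the post; repeated mentions count once, and multiple distinct emotion
#' groups in one post are all set. Posts must have passed
#' [filter_posts()]: a post with no emotion indicator raises an
#' internal-consistency error.
#'
#' @param posts kept posts from [filter_posts()] (or any data.frame with
#'   `id`, `channel`, `text`).
#' @param lexicon an `emo_lexicon`.
#' @return a [transaction_set()] over the 47 catalog items.
#' @export
code_posts <- function(posts, lexicon) {
  catalog <- lexicon$catalog
  mm <- attr(posts, "item_matrix")
  if (is.null(mm)) mm <- match_posts(posts, lexicon)$items
  if (nrow(mm) > 0) {
    no_emo <- rowSums(mm[, catalog$emotion_groups, drop = FALSE]) == 0
    if (any(no_emo)) {
      stop("internal-consistency error: post(s) without any emotion ",
           "indicator reached coding (filter contract violated): ",
           paste(utils::head(posts$id[no_emo], 5), collapse = ", "))
    }
  }
  transaction_set(mm, post_id = posts$id, channel = posts$channel,
                  items = catalog$all_items)
}

#' Write / read a transaction set as CSV
#'
#' Header `post_id,channel,<47 item columns>` with 0/1 entries.
#'
#' @param transactions a `transaction_set`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `transaction_set` (reader).
#' @export
write_transactions <- function(transactions, path) {
  df <- data.frame(post_id = transactions$post_id,
                   channel = transactions$channel,
                   transactions$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  item_cols <- setdiff(names(df), c("post_id", "channel"))
  transaction_set(as.matrix(df[, item_cols, drop = FALSE]),
                  post_id = as.character(df$post_id),
                  channel = df$channel, items = item_cols)
}

#' Write a filter report as JSON
#'
#' @param report a [filter_report()].
#' @param path JSON path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
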