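# Frequency analysis: per-channel characteristic tables and overall
# emotion-group frequencies.

#' Round half away from zero
#'
#' Plain half-up rounding (0.05 -> 0.1 at one decimal), as used in the
#' printed percentage tables, rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-channel frequency table from raw counts
#'
#' @param counts matrix or data.frame of post counts with one row per
#'   item (rownames = item identifiers) and one column per channel.
#' @return data.frame with `item`, `total`, and per-channel `<ch>_n` and
#'   `<ch>_pct` columns; row percentages are half-up to one decimal.
#' @examples
#' channel_table_from_counts(matrix(c(5450, 6053, 9802, 156), 1,
#'   dimnames = list("leukemia", c("blog", "cafe", "twitter", "board"))))
#' @export
channel_table_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have item rownames and channel colnames")
  }
  total <- rowSums(counts)
  out <- data.frame(item = rownames(counts), total = total,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (ch in colnames(counts)) {
    out[[paste0(ch, "_n")]] <- counts[, ch]
    pct <- ifelse(total > 0, counts[, ch] / total * 100, 0)
    out[[paste0(ch, "_pct")]] <- round_half_up(pct, 1)
  }
  out
}

#' Per-channel frequency table of items
#'
#' For each requested item, counts the posts per channel with the
#' indicator set, in the shape of the published channel characteristics
#' table: total, per-channel counts, and per-channel row percentages
#' (half-up, one decimal).
#'
#' @param transactions a `transaction_set`.
#' @param items items to tabulate; defaults to the gender, age, and
#'   cancer-type factor items.
#' @param catalog an [item_catalog()].
#' @return data.frame as in [channel_table_from_counts()].
#' @export
channel_table <- function(transactions, items = NULL,
                          catalog = item_catalog()) {
  if (is.null(items)) {
    items <- names(catalog$factor_category)[
      catalog$factor_category %in% c("gender", "age", "cancer_type")]
  }
  if (!all(items %in% transactions$items)) {
    stop("requested item(s) not in the transaction set: ",
         paste(setdiff(items, transactions$items), collapse = ", "))
  }
  channels <- intersect(CHANNELS, unique(transactions$channel))
  if (length(channels) == 0) channels <- CHANNELS[1]
  counts <- sapply(channels, function(ch) {
    rows <- transactions$channel == ch
    colSums(transactions$matrix[rows, items, drop = FALSE])
  })
  counts <- matrix(counts, nrow = length(items),
                   dimnames = list(items, channels))
  channel_table_from_counts(counts)
}

#' Emotion-group frequencies from counts
#'
#' @param counts named vector of post counts per emotion group.
#' @param n_posts total number of posts (the percentage denominator;
#'   percentages may sum above 100 because posts are multi-label).
#' @return data.frame `emotion_group`, `count`, `percent` (half-up, one
#'   decimal), sorted by count descending.
#' @examples
#' emotion_frequencies_from_counts(
#'   c(HG = 149558, FAO = 145179, SDLG = 126496, AD = 25560), 321339)
#' @export
emotion_frequencies_from_counts <- function(counts, n_posts) {
  if (n_posts <= 0) stop("n_posts must be positive")
  out <- data.frame(emotion_group = names(counts),
                    count = as.integer(counts),
                    percent = round_half_up(counts / n_posts * 100, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$count, out$emotion_group), , drop = FALSE]
}

#' Emotion-group frequencies of a transaction set
#'
#' @param transactions a `transaction_set` over the catalog items.
#' @param catalog an [item_catalog()].
#' @return as [emotion_frequencies_from_counts()].
#' @export
emotion_frequencies <- function(transactions, catalog = item_catalog()) {
  if (transactions$n_posts == 0) stop("no posts: frequencies undefined")
  counts <- colSums(transactions$matrix[, catalog$emotion_groups,
                                        drop = FALSE])
  emotion_frequencies_from_counts(counts, transactions$n_posts)
}

#' Channel shares from counts
#'
#' @param counts named vector of post counts per channel.
#' @return data.frame `channel`, `n`, `percent` (of all posts, half-up
#'   one decimal), in canonical channel order.
#' @export
channel_shares_from_counts <- function(counts) {
  counts <- stats::setNames(as.numeric(counts), names(counts))
  total <- sum(counts)
  if (total <= 0) stop("no posts: shares undefined")
  ord <- intersect(CHANNELS, names(counts))
  counts <- counts[c(ord, setdiff(names(counts), ord))]
  data.frame(channel = names(counts), n = as.integer(counts),
             percent = round_half_up(counts / total * 100, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Channel shares of a transaction set
#'
#' @param transactions a `transaction_set`.
#' @return as [channel_shares_from_counts()].
#' @export
channel_shares <- function(transactions) {
  channel_shares_from_counts(table(transactions$channel))
}
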