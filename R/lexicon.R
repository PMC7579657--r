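# Lexicon: ontology-derived term -> concept -> analysis item (or role
# marker), plus token-sequence dictionary matching.

#' Normalize a term or token
#'
#' Case-folds and collapses internal whitespace. All lexicon terms and all
#' matched text pass through the same normalization, so matching is
#' case-insensitive and whitespace-insensitive.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Tokenize free text
#'
#' Lower-cases, strips leading/trailing punctuation from each token, and
#' splits on whitespace. No stemming or morphological analysis is applied:
#' the matcher operates on surface tokens.
#'
#' @param text character vector of raw post texts.
#' @return list of character token vectors (one per input element).
#' @export
tokenize <- function(text) {
  text <- tolower(text)
  toks <- strsplit(text, "[[:space:]]+")
  lapply(toks, function(tk) {
    tk <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tk)
    tk[nzchar(tk)]
  })
}

#' Read a lexicon file
#'
#' The lexicon is a UTF-8 TSV with header `term<TAB>concept<TAB>item`.
#' `item` is one of the 47 analysis items, one of the nine ontology
#' emotion classes (mapped to its emotion group on load), or a role
#' marker (`cancer_keyword`, `stop_keyword`, `ad_keyword`). Duplicate
#' (term, item) rows are deduplicated; a term mapping to two different
#' items is an error.
#'
#' @param path path to the TSV file.
#' @param catalog an [item_catalog()].
#' @return An object of class `emo_lexicon`: list with `entries`
#'   (data.frame term/concept/item/n_tokens) and `catalog`.
#' @examples
#' lex <- read_lexicon(system.file("extdata", "standin_lexicon.tsv",
#'                                 package = "emomine"))
#' nrow(lex$entries)
#' @export
read_lexicon <- function(path, catalog = item_catalog()) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("term", "concept", "item")
  if (!all(need %in% names(df))) {
    stop("lexicon format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[, need]
  df$term[is.na(df$term)] <- ""
  df$term <- normalize_term(df$term)
  if (any(!nzchar(df$term))) {
    stop("lexicon validation error: empty term after normalization (row ",
         paste(which(!nzchar(df$term)), collapse = ", "), ")")
  }
  # An emotion-class item name stands for its group.
  cls <- df$item %in% names(catalog$emotion_class_map)
  df$item[cls] <- unname(catalog$emotion_class_map[df$item[cls]])

  known <- c(catalog$all_items, catalog$role_markers)
  bad <- setdiff(unique(df$item), known)
  if (length(bad) > 0) {
    stop("lexicon validation error: unknown item(s): ",
         paste(bad, collapse = ", "))
  }
  df <- unique(df[, c("term", "concept", "item")])
  # a term may not map to two different items
  amb <- tapply(df$item, df$term, function(x) length(unique(x)))
  amb <- names(amb)[amb > 1]
  if (length(amb) > 0) {
    offenders <- df[df$term %in% amb, ]
    stop("lexicon validation error: ambiguous term(s) mapping to ",
         "multiple items: ",
         paste(sprintf("'%s' -> {%s}", amb,
                       vapply(amb, function(t) {
                         paste(unique(df$item[df$term == t]), collapse = ", ")
                       }, character(1))),
               collapse = "; "))
  }
  # deduplicate identical (term, item) pairs possibly differing in concept
  df <- df[!duplicated(df[, c("term", "item")]), ]
  df$n_tokens <- lengths(strsplit(df$term, " ", fixed = TRUE))
  rownames(df) <- NULL
  structure(list(entries = df, catalog = catalog), class = "emo_lexicon")
}

#' @export
print.emo_lexicon <- function(x, ...) {
  e <- x$entries
  n_items <- length(unique(e$item[e$item %in% x$catalog$all_items]))
  cat(sprintf("Lexicon: %d terms covering %d/47 analysis items (%d stop, %d ad terms)\n",
              nrow(e), n_items,
              sum(e$item == "stop_keyword"), sum(e$item == "ad_keyword")))
  invisible(x)
}

#' Terms attached to one item
#'
#' @param lexicon an `emo_lexicon`.
#' @param item an analysis item or role marker.
#' @return character vector of normalized terms (possibly empty).
#' @export
terms_for_item <- function(lexicon, item) {
  lexicon$entries$term[lexicon$entries$item == item]
}

# Bulk matcher. `texts` are normalized, space-joined token strings.
# A term matches iff its tokens occur as a contiguous subsequence, which
# for space-joined text is a substring match on token boundaries. All
# matching entries contribute (set union; a longer multi-token term never
# suppresses a shorter term that is its own lexicon entry).
# Returns an n x n_targets logical matrix.
match_term_matrix <- function(texts, lexicon, targets = NULL) {
  e <- lexicon$entries
  if (is.null(targets)) targets <- unique(e$item)
  padded <- paste0(" ", texts, " ")
  out <- matrix(FALSE, nrow = length(texts), ncol = length(targets),
                dimnames = list(NULL, targets))
  e <- e[e$item %in% targets, ]
  for (i in seq_len(nrow(e))) {
    hit <- grepl(paste0(" ", e$term[i], " "), padded, fixed = TRUE)
    if (any(hit)) out[, e$item[i]] <- out[, e$item[i]] | hit
  }
  out
}

# Normalize a posts data.frame to joined token strings.
post_match_strings <- function(text) {
  vapply(tokenize(text), paste, character(1), collapse = " ")
}

#' Match lexicon items in a token sequence
#'
#' Returns the set of distinct analysis items whose terms occur in the
#' token sequence, and separately the set of role markers
#' (`cancer_keyword`, `stop_keyword`, `ad_keyword`) that occur.
#' Multi-token terms match contiguous token runs; repeated mentions
#' contribute nothing beyond set membership (count-once semantics).
#'
#' @param tokens character vector of tokens (normalized as by
#'   [tokenize()]; they are re-normalized defensively).
#' @param lexicon an `emo_lexicon`.
#' @return list with `items` (sorted character vector, subset of the 47
#'   catalog items) and `roles` (sorted subset of the role markers).
#' @examples
#' lex <- read_lexicon(system.file("extdata", "standin_lexicon.tsv",
#'                                 package = "emomine"))
#' match_items(c("breast", "cancer", "hope", "hope"), lex)
#' @export
match_items <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "emo_lexicon"))
  tokens <- normalize_term(as.character(tokens))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    return(list(items = character(0), roles = character(0)))
  }
  hits <- match_term_matrix(paste(tokens, collapse = " "), lexicon)
  found <- colnames(hits)[hits[1, ]]
  # catalog order: deterministic and locale-independent
  list(items = intersect(lexicon$catalog$all_items, found),
       roles = intersect(lexicon$catalog$role_markers, found))
}
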