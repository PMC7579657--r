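# Fixtures built in code: ad-hoc lexicons and tiny corpora.

standin_lexicon_path <- function() {
  system.file("extdata", "standin_lexicon.tsv", package = "emomine")
}

standin_lexicon <- function() read_lexicon(standin_lexicon_path())

# Write a lexicon TSV from a data.frame(term, concept, item) and read it
# back; returns the lexicon unless read_lexicon errors.
lexicon_from_rows <- function(rows) {
  tf <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  utils::write.table(rows, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  read_lexicon(tf)
}

lexicon_rows <- function(...) {
  rows <- list(...)
  data.frame(term = vapply(rows, `[[`, character(1), 1),
             concept = vapply(rows, `[[`, character(1), 2),
             item = vapply(rows, `[[`, character(1), 3),
             stringsAsFactors = FALSE)
}

# Minimal working lexicon used by coding tests: a generic cancer term,
# two emotion groups, two factors, one stop and one ad term.
mini_lexicon <- function() {
  lexicon_from_rows(lexicon_rows(
    c("cancer", "cancer_type_superclass", "cancer_keyword"),
    c("hope", "hope", "HG"),
    c("gratitude", "gratitude", "HG"),
    c("anxiety", "anxiety", "FAO"),
    c("depression", "depression", "SDLG"),
    c("surgery", "treatment", "surgery"),
    c("40s", "age", "age_40s"),
    c("breast cancer", "cancer_type", "breast_cancer"),
    c("horoscope", "stop", "stop_keyword"),
    c("detoxification", "advertising", "ad_keyword")
  ))
}

posts_df <- function(texts, channel = "blog", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%03d", seq_along(texts))
  data.frame(id = ids, channel = rep_len(channel, length(texts)),
             text = texts, stringsAsFactors = FALSE)
}

# transaction set over arbitrary fake items from a 0/1 matrix
ts_from_matrix <- function(mat, channel = "blog") {
  transaction_set(mat, channel = rep_len(channel, nrow(mat)))
}

# random transactions over k items with heterogeneous densities
random_transactions <- function(n, items, p = NULL) {
  if (is.null(p)) p <- stats::runif(length(items), 0.1, 0.6)
  mat <- matrix(stats::runif(n * length(items)) < rep(p, each = n),
                nrow = n, dimnames = list(NULL, items)) * 1L
  mat
}
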