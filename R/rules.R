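# Apriori frequent-itemset mining and factor -> emotion association
# rules with support, confidence, and lift.

itemset_key <- function(items) paste(sort(items), collapse = "\u001f")

as_item_matrix <- function(transactions) {
  if (inherits(transactions, "transaction_set")) {
    transactions$matrix > 0
  } else if (is.matrix(transactions)) {
    transactions > 0
  } else {
    stop("transactions must be a transaction_set or a 0/1 matrix")
  }
}

#' Mine frequent itemsets with the Apriori algorithm
#'
#' Level-wise candidate generation with downward-closure pruning: every
#' `k`-candidate is built from two frequent `(k-1)`-sets sharing a
#' `(k-2)`-prefix and is kept only if all of its `(k-1)`-subsets are
#' frequent. Returns exactly the itemsets with support `>= min_support`,
#' in deterministic order (size, then lexicographic items).
#'
#' @param transactions a `transaction_set` or 0/1 matrix with item
#'   columns.
#' @param min_support minimum support, in (0, 1].
#' @param max_size optional cap on itemset size (e.g. 2 when only
#'   single-antecedent rules are needed).
#' @return object of class `frequent_itemsets`: data.frame with
#'   `itemset` (list column of sorted character vectors), `size`, and
#'   `support`; attributes `min_support` and `n_posts`.
#' @export
apriori <- function(transactions, min_support, max_size = Inf) {
  if (min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]; a non-positive threshold would ",
         "enumerate all 2^k itemsets")
  }
  M <- as_item_matrix(transactions)
  n <- nrow(M)
  empty <- data.frame(size = integer(0), support = numeric(0))
  empty$itemset <- list()
  empty <- empty[, c("itemset", "size", "support")]
  if (n == 0) {
    return(structure(empty, class = c("frequent_itemsets", "data.frame"),
                     min_support = min_support, n_posts = 0L))
  }
  sup1 <- colMeans(M)
  f1 <- sort(names(sup1)[sup1 >= min_support])
  sets <- list()
  supports <- numeric(0)
  level <- lapply(f1, identity)
  level_sup <- unname(sup1[f1])
  freq_keys <- new.env(parent = emptyenv())
  for (it in f1) assign(it, TRUE, envir = freq_keys)

  k <- 1L
  while (length(level) > 0) {
    sets <- c(sets, level)
    supports <- c(supports, level_sup)
    if (k + 1L > max_size) break
    # candidate generation: join sets sharing the first k-1 items
    prefixes <- vapply(level, function(s) {
      paste(s[-length(s)], collapse = "\u001f")
    }, character(1))
    lasts <- vapply(level, function(s) s[length(s)], character(1))
    cand <- list()
    for (pre in unique(prefixes)) {
      idx <- which(prefixes == pre)
      if (length(idx) < 2) next
      tails <- sort(lasts[idx])
      base <- level[[idx[1]]][-k]
      for (a in seq_len(length(tails) - 1)) {
        for (b in seq((a + 1), length(tails))) {
          cand[[length(cand) + 1L]] <- c(base, tails[a], tails[b])
        }
      }
    }
    if (length(cand) == 0) break
    # downward-closure pruning
    keep <- vapply(cand, function(s) {
      all(vapply(seq_along(s), function(i) {
        exists(itemset_key(s[-i]), envir = freq_keys, inherits = FALSE)
      }, logical(1)))
    }, logical(1))
    cand <- cand[keep]
    if (length(cand) == 0) break
    cand_sup <- vapply(cand, function(s) {
      sum(Reduce(`&`, lapply(s, function(it) M[, it]))) / n
    }, numeric(1))
    ok <- cand_sup >= min_support
    level <- cand[ok]
    level_sup <- cand_sup[ok]
    if (length(level) > 0) {
      ord <- order(vapply(level, itemset_key, character(1)))
      level <- level[ord]
      level_sup <- level_sup[ord]
      for (s in level) assign(itemset_key(s), TRUE, envir = freq_keys)
    }
    k <- k + 1L
  }
  if (length(sets) == 0) {
    return(structure(empty, class = c("frequent_itemsets", "data.frame"),
                     min_support = min_support, n_posts = n))
  }
  sizes <- lengths(sets)
  keys <- vapply(sets, itemset_key, character(1))
  ord <- order(sizes, keys)
  out <- data.frame(size = sizes[ord], support = supports[ord])
  out$itemset <- sets[ord]
  out <- out[, c("itemset", "size", "support")]
  rownames(out) <- NULL
  structure(out, class = c("frequent_itemsets", "data.frame"),
            min_support = min_support, n_posts = n)
}

#' @export
print.frequent_itemsets <- function(x, ...) {
  cat(sprintf("%d frequent itemsets (min_support = %g, %d posts)\n",
              nrow(x), attr(x, "min_support"), attr(x, "n_posts")))
  if (nrow(x) > 0) {
    show <- utils::head(x, 10)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  {%s}: %.4f\n",
                  paste(show$itemset[[i]], collapse = ", "),
                  show$support[i]))
    }
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Generate factor -> emotion association rules
#'
#' Emits every rule whose antecedent is a non-empty set of factor items
#' and whose consequent is a single emotion group, such that antecedent
#' plus consequent is frequent and confidence `>= min_confidence`.
#' `support` is the support of antecedent plus consequent,
#' `confidence = support(rule) / support(antecedent)`, and
#' `lift = confidence / support(consequent)` (>1 indicates positive
#' association, about 1 independence).
#'
#' @param frequent a `frequent_itemsets` object from [apriori()].
#' @param min_confidence minimum confidence, in `[0, 1]`.
#' @param catalog an [item_catalog()] (or any list with
#'   `emotion_groups` and `factor_groups`) defining the rule roles.
#' @return object of class `association_rules`: data.frame with
#'   `antecedent` (list column), `antecedent_str` (items joined by `|`),
#'   `consequent`, `support`, `confidence`, `lift`, ordered by
#'   consequent, then lift, support, antecedent.
#' @export
generate_rules <- function(frequent, min_confidence = 0.1,
                           catalog = item_catalog()) {
  stopifnot(inherits(frequent, "frequent_itemsets"))
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must be in [0, 1]")
  }
  sup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(frequent))) {
    assign(itemset_key(frequent$itemset[[i]]), frequent$support[i],
           envir = sup)
  }
  lookup <- function(items) {
    get0(itemset_key(items), envir = sup, ifnotfound = NA_real_)
  }
  rows <- vector("list", nrow(frequent))
  for (i in seq_len(nrow(frequent))) {
    s <- frequent$itemset[[i]]
    if (length(s) < 2) next
    emo <- intersect(s, catalog$emotion_groups)
    if (length(emo) != 1) next
    ant <- setdiff(s, emo)
    if (!all(ant %in% catalog$factor_groups)) next
    sup_ant <- lookup(ant)   # frequent by downward closure
    sup_con <- lookup(emo)
    if (is.na(sup_con) || sup_con == 0) {
      message("skipping rule {", paste(ant, collapse = ", "), "} => {",
              emo, "}: consequent support is zero, lift undefined")
      next
    }
    conf <- frequent$support[i] / sup_ant
    if (conf < min_confidence) next
    rows[[i]] <- data.frame(
      antecedent_str = paste(sort(ant), collapse = "|"),
      consequent = emo,
      support = frequent$support[i],
      confidence = conf,
      lift = conf / sup_con,
      stringsAsFactors = FALSE
    )
    rows[[i]]$antecedent <- list(sort(ant))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(antecedent_str = character(0),
                      consequent = character(0), support = numeric(0),
                      confidence = numeric(0), lift = numeric(0),
                      stringsAsFactors = FALSE)
    out$antecedent <- list()
  } else {
    out <- do.call(rbind, rows)
  }
  con_rank <- match(out$consequent, catalog$emotion_groups)
  ord <- order(con_rank, -out$lift, -out$support, out$antecedent_str)
  out <- out[ord, c("antecedent", "antecedent_str", "consequent",
                    "support", "confidence", "lift")]
  rownames(out) <- NULL
  structure(out, class = c("association_rules", "data.frame"),
            n_posts = attr(frequent, "n_posts"))
}

#' @export
print.association_rules <- function(x, ...) {
  cat(sprintf("%d association rules\n", nrow(x)))
  show <- utils::head(x, 10)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  {%s} => {%s}  supp %.3f conf %.3f lift %.3f\n",
                gsub("|", ", ", show$antecedent_str[i], fixed = TRUE),
                show$consequent[i], show$support[i], show$confidence[i],
                show$lift[i]))
  }
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Top rules by lift per emotion group
#'
#' For each consequent emotion group, the `k` rules with the highest
#' lift; ties broken by higher support, then lexicographic antecedent.
#'
#' @param rules an `association_rules` object.
#' @param k rules to keep per group (>= 1).
#' @param per optional single emotion group to restrict to.
#' @return an `association_rules` data.frame.
#' @export
top_rules_by_lift <- function(rules, k = 5, per = NULL) {
  stopifnot(k >= 1)
  groups <- if (is.null(per)) unique(rules$consequent) else per
  picked <- lapply(groups, function(g) {
    r <- rules[rules$consequent == g, , drop = FALSE]
    r <- r[order(-r$lift, -r$support, r$antecedent_str), , drop = FALSE]
    utils::head(r, k)
  })
  out <- do.call(rbind, c(picked, list(rules[0, , drop = FALSE])))
  rownames(out) <- NULL
  structure(out, class = c("association_rules", "data.frame"),
            n_posts = attr(rules, "n_posts"))
}

#' Compute the mined lift of one rule directly from transactions
#'
#' @param transactions a `transaction_set` or 0/1 matrix.
#' @param antecedent character vector of items.
#' @param consequent single item.
#' @return named list with `support`, `confidence`, `lift` (NA when the
#'   antecedent or consequent never occurs).
#' @export
mined_lift <- function(transactions, antecedent, consequent) {
  M <- as_item_matrix(transactions)
  a <- Reduce(`&`, lapply(antecedent, function(it) M[, it]))
  e <- M[, consequent]
  pa <- mean(a); pe <- mean(e); pae <- mean(a & e)
  if (pa == 0 || pe == 0) {
    return(list(support = pae, confidence = NA_real_, lift = NA_real_))
  }
  list(support = pae, confidence = pae / pa, lift = (pae / pa) / pe)
}

#' Bootstrap standard error of a rule's lift
#'
#' Nonparametric bootstrap over posts (rows).
#'
#' @inheritParams mined_lift
#' @param n_boot number of bootstrap resamples.
#' @param seed optional seed for the resampling.
#' @return standard error of the lift estimate.
#' @export
bootstrap_lift_se <- function(transactions, antecedent, consequent,
                              n_boot = 200, seed = NULL) {
  M <- as_item_matrix(transactions)
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- Reduce(`&`, lapply(antecedent, function(it) M[, it]))
  e <- M[, consequent]
  n <- length(a)
  lifts <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    pa <- mean(a[idx]); pe <- mean(e[idx]); pae <- mean(a[idx] & e[idx])
    if (pa == 0 || pe == 0) NA_real_ else (pae / pa) / pe
  }, numeric(1))
  stats::sd(lifts, na.rm = TRUE)
}

#' Write association rules to CSV (and optionally full-precision JSONL)
#'
#' The CSV carries antecedent items joined by `|` and support,
#' confidence, and lift half-up rounded to three decimals, matching the
#' printed rule tables; the JSONL keeps full precision.
#'
#' @param rules an `association_rules` object.
#' @param path CSV path.
#' @param jsonl_path optional JSONL path.
#' @export
write_rules <- function(rules, path, jsonl_path = NULL) {
  df <- data.frame(
    antecedent = rules$antecedent_str,
    consequent = rules$consequent,
    support = sprintf("%.3f", round_half_up(rules$support, 3)),
    confidence = sprintf("%.3f", round_half_up(rules$confidence, 3)),
    lift = sprintf("%.3f", round_half_up(rules$lift, 3)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonl_path)) {
    lines <- vapply(seq_len(nrow(rules)), function(i) {
      jsonlite::toJSON(list(antecedent = rules$antecedent[[i]],
                            consequent = rules$consequent[i],
                            support = rules$support[i],
                            confidence = rules$confidence[i],
                            lift = rules$lift[i]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, jsonl_path)
  }
  invisible(path)
}
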