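test_that("apriori finds exactly the frequent itemsets on a hand example", {
  # transactions: AB, AB, AC, B at min_support 0.5
  m <- matrix(c(1, 1, 0,
                1, 1, 0,
                1, 0, 1,
                0, 1, 0), nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  fi <- apriori(m, 0.5)
  expect_equal(lapply(fi$itemset, identity),
               list("A", "B", c("A", "B")))
  expect_equal(fi$support, c(0.75, 0.75, 0.5))
  # boundary threshold: only itemsets in every post
  all4 <- apriori(m, 1.0)
  expect_equal(nrow(all4), 0)
  m2 <- cbind(m, D = 1)
  expect_equal(lapply(apriori(m2, 1.0)$itemset, identity), list("D"))
})

test_that("apriori rejects degenerate thresholds and empty input", {
  m <- matrix(1, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(apriori(m, 0), "min_support")
  expect_error(apriori(m, -0.1), "min_support")
  empty <- matrix(0L, 0, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(nrow(apriori(empty, 0.5)), 0)
})

test_that("apriori equals brute-force enumeration on random corpora", {
  set.seed(47)
  for (trial in 1:25) {
    k <- sample(6:12, 1)
    n <- sample(15:60, 1)
    mat <- random_transactions(n, LETTERS[1:k])
    ms <- stats::runif(1, 0.05, 0.5)
    expect_matches_bruteforce(apriori(mat, ms), mat, ms)
  }
})

test_that("mined supports are anti-monotone and max_size caps the search", {
  set.seed(53)
  mat <- random_transactions(200, letters[1:10])
  fi <- apriori(mat, 0.05)
  keys <- vapply(fi$itemset, paste, character(1), collapse = "|")
  sup <- stats::setNames(fi$support, keys)
  for (i in which(fi$size > 1)) {
    s <- fi$itemset[[i]]
    for (j in seq_along(s)) {
      parent <- paste(s[-j], collapse = "|")
      expect_gte(sup[[parent]], fi$support[i])
    }
  }
  capped <- apriori(mat, 0.05, max_size = 2)
  expect_lte(max(capped$size), 2)
  expect_equal(capped$support[capped$size <= 2],
               fi$support[fi$size <= 2])
})

test_that("rules carry the support/confidence/lift identities", {
  # 4 posts: {f1,e1} x2, {e1} 0 more, e1 in 2 of 4 posts
  m <- matrix(0L, 4, 47, dimnames = list(NULL, item_catalog()$all_items))
  m[1:2, "surgery"] <- 1L
  m[1:2, "HG"] <- 1L
  m[3:4, "FAO"] <- 1L
  fi <- apriori(transaction_set(m), 0.25)
  rules <- generate_rules(fi, min_confidence = 0.1)
  r <- rules[rules$antecedent_str == "surgery" & rules$consequent == "HG", ]
  expect_equal(r$confidence, 1.0)
  expect_equal(r$lift, 2.0)
  expect_equal(r$support, 0.5)
})

test_that("rule roles are enforced: factor antecedents, emotion consequents", {
  set.seed(61)
  cfg <- default_generator_config(n_total = 1500, seed = 61)
  lex <- standin_lexicon()
  ts <- code_posts(filter_posts(generate_corpus(cfg, lex), lex)$posts, lex)
  rules <- generate_rules(apriori(ts, 0.01), 0.05)
  catalog <- item_catalog()
  expect_gt(nrow(rules), 0)
  expect_true(all(rules$consequent %in% catalog$emotion_groups))
  expect_true(all(unlist(rules$antecedent) %in% catalog$factor_groups))
  expect_true(all(lengths(rules$antecedent) >= 1))
  # lift identity to machine precision on every emitted rule
  sup_con <- colMeans(ts$matrix[, catalog$emotion_groups] > 0)
  expect_true(all(abs(rules$lift -
                        rules$confidence / sup_con[rules$consequent]) < 1e-12))
  # support(rule) <= support(antecedent) via confidence <= 1
  expect_true(all(rules$confidence <= 1 + 1e-12))
})

test_that("independent items mine to lift near 1", {
  cfg <- generator_config(
    n_posts = c(blog = 8000),
    factor_prevalence = c(surgery = 0.4, male = 0.3),
    emotion_model = list(
      baseline = c(HG = 0.45, FAO = 0.4, SDLG = 0.35, AD = 0.1),
      effects = list()),
    seed = 71)
  lex <- standin_lexicon()
  ts <- code_posts(filter_posts(generate_corpus(cfg, lex), lex)$posts, lex)
  got <- mined_lift(ts, "surgery", "HG")
  expect_lt(abs(got$lift - 1), 0.1)
})

test_that("top_rules_by_lift ranks by lift with documented tie-breaks", {
  mk <- function(ant, con, sup, conf, lift) {
    df <- data.frame(antecedent_str = ant, consequent = con, support = sup,
                     confidence = conf, lift = lift,
                     stringsAsFactors = FALSE)
    df$antecedent <- list(strsplit(ant, "|", fixed = TRUE)[[1]])
    df
  }
  rules <- do.call(rbind, list(
    mk("surgery", "HG", 0.02, 0.5, 1.9),
    mk("male", "HG", 0.01, 0.5, 1.9),      # tie on lift: lower support
    mk("female", "HG", 0.02, 0.5, 1.9),    # tie on lift+support: by name
    mk("chemotherapy", "HG", 0.03, 0.6, 2.5),
    mk("cam", "HG", 0.01, 0.2, 1.1),
    mk("surgery", "AD", 0.01, 0.2, 1.4)
  ))
  class(rules) <- c("association_rules", "data.frame")
  top <- top_rules_by_lift(rules, k = 3, per = "HG")
  expect_equal(top$antecedent_str, c("chemotherapy", "female", "surgery"))
  # fewer than k rules: return what exists
  expect_equal(nrow(top_rules_by_lift(rules, k = 5, per = "AD")), 1)
})

test_that("rule CSV is rounded to 3 decimals, JSONL keeps full precision", {
  m <- matrix(0L, 3, 47, dimnames = list(NULL, item_catalog()$all_items))
  m[1:2, "surgery"] <- 1L
  m[1:2, "HG"] <- 1L
  m[3, "FAO"] <- 1L
  rules <- generate_rules(apriori(transaction_set(m), 0.3), 0.1)
  csvf <- withr::local_tempfile(fileext = ".csv")
  jf <- withr::local_tempfile(fileext = ".jsonl")
  write_rules(rules, csvf, jf)
  csv <- utils::read.csv(csvf, stringsAsFactors = FALSE)
  expect_equal(csv$lift[1], round_half_up(rules$lift[1], 3))
  js <- jsonlite::fromJSON(readLines(jf)[1])
  expect_equal(js$lift, rules$lift[1], tolerance = 1e-15)
})
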