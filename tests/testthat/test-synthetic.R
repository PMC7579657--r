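test_that("generation is deterministic given config and seed", {
  cfg <- default_generator_config(n_total = 400, seed = 11)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$text, b$text)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c2 <- generate_corpus(cfg, seed = 12)
  expect_false(identical(a$text, c2$text))
})

test_that("null model yields emotions near their conditioned marginals", {
  cfg <- generator_config(
    n_posts = c(blog = 100),
    factor_prevalence = c(surgery = 0.3),
    emotion_model = list(
      baseline = c(HG = 0.5, FAO = 0.5, SDLG = 0.5, AD = 0.5),
      effects = list()),
    seed = 7)
  corp <- generate_corpus(cfg)
  truth <- attr(corp, "truth")
  # conditioning on >= 1 emotion raises 0.5 to 0.5 / (1 - 0.5^4)
  expected <- expected_emotion_marginals(cfg)
  expect_equal(unname(expected), rep(0.5 / (1 - 0.5^4), 4))
  obs <- colMeans(truth[, c("HG", "FAO", "SDLG", "AD")])
  se <- sqrt(expected * (1 - expected) / 100)
  expect_true(all(abs(obs - expected) < 3.5 * se))
})

test_that("ad contamination plants advertising keywords at the set rate", {
  cfg <- generator_config(
    n_posts = c(cafe = 1000),
    factor_prevalence = c(surgery = 0.2),
    emotion_model = list(
      baseline = c(HG = 0.4, FAO = 0.3, SDLG = 0.2, AD = 0.1),
      effects = list()),
    contamination = c(ad = 0.1, no_emotion = 0),
    seed = 3)
  lex <- standin_lexicon()
  corp <- generate_corpus(cfg, lex)
  is_ad <- attr(corp, "ad")
  # binomial(1000, 0.1): 3 sigma is ~28.5
  expect_gt(sum(is_ad), 100 - 29)
  expect_lt(sum(is_ad), 100 + 29)
  # flagged posts really carry an ad term
  mm <- vapply(tokenize(corp$text[is_ad]), function(tk) {
    "ad_keyword" %in% match_items(tk, lex)$roles
  }, logical(1))
  expect_true(all(mm))
})

test_that("no_emotion contamination reinstates zero-emotion posts", {
  cfg <- generator_config(
    n_posts = c(board = 800),
    factor_prevalence = c(surgery = 0.2),
    emotion_model = list(
      baseline = c(HG = 0.4, FAO = 0.3, SDLG = 0.2, AD = 0.1),
      effects = list()),
    contamination = c(ad = 0, no_emotion = 0.2),
    seed = 9)
  truth <- attr(generate_corpus(cfg), "truth")
  n_zero <- sum(rowSums(truth[, c("HG", "FAO", "SDLG", "AD")]) == 0)
  expect_gt(n_zero, 160 - 3 * sqrt(800 * 0.2 * 0.8))
  expect_lt(n_zero, 160 + 3 * sqrt(800 * 0.2 * 0.8))
})

test_that("twitter posts respect the 140-character limit", {
  cfg <- default_generator_config(n_total = 3000, seed = 5)
  corp <- generate_corpus(cfg)
  tw <- corp$text[corp$channel == "twitter"]
  expect_gt(length(tw), 0)
  expect_true(all(nchar(tw, type = "chars") <= 140))
  # unsatisfiable limit is a generation error naming the post
  dense <- generator_config(
    n_posts = c(twitter = 5),
    factor_prevalence = stats::setNames(
      rep(1, 43), item_catalog()$factor_groups),
    emotion_model = list(
      baseline = c(HG = 0.9, FAO = 0.9, SDLG = 0.9, AD = 0.9),
      effects = list()),
    seed = 2)
  expect_error(generate_corpus(dense), "140-character.*twitter_00001|twitter_00001.*140")
})

test_that("expected_lift matches hand enumeration and independence", {
  base <- list(baseline = c(HG = 0.2, FAO = 0.3, SDLG = 0.3, AD = 0.1),
               effects = list(HG = c(surgery = 4)))
  cfg <- generator_config(n_posts = c(blog = 100),
                          factor_prevalence = c(surgery = 0.5),
                          emotion_model = base, seed = 1)
  # two-configuration sum by hand: p(HG|f) = plogis(qlogis(.2) + log 4) = .5
  p1 <- stats::plogis(stats::qlogis(0.2) + log(4))
  marg <- 0.5 * p1 + 0.5 * 0.2
  expect_equal(expected_lift(cfg, "surgery", "HG",
                             condition_on_emotion = FALSE),
               p1 / marg, tolerance = 1e-12)
  expect_equal(p1 / marg, 10 / 7, tolerance = 1e-12)

  # all effects = 1: lift is exactly 1, conditioned or not
  null_cfg <- generator_config(n_posts = c(blog = 100),
                               factor_prevalence = c(surgery = 0.5),
                               emotion_model = list(
                                 baseline = base$baseline, effects = list()),
                               seed = 1)
  expect_equal(expected_lift(null_cfg, "surgery", "HG"), 1, tolerance = 1e-12)
  # empty antecedent: lift 1 by construction
  expect_equal(expected_lift(cfg, character(0), "HG"), 1, tolerance = 1e-12)
})

test_that("expected_lift refuses runaway enumeration", {
  prev <- stats::setNames(rep(0.1, 43), item_catalog()$factor_groups)
  eff <- stats::setNames(rep(2, 21), item_catalog()$factor_groups[1:21])
  cfg <- generator_config(n_posts = c(blog = 10), factor_prevalence = prev,
                          emotion_model = list(
                            baseline = c(HG = 0.3, FAO = 0.3, SDLG = 0.3,
                                         AD = 0.1),
                            effects = list(HG = eff)),
                          seed = 1)
  expect_error(expected_lift(cfg, "male", "HG"), "20 active factors")
})

test_that("a planted effect produces empirical lift above 1", {
  cfg <- generator_config(
    n_posts = c(blog = 5000),
    factor_prevalence = c(radiation_therapy = 0.2, surgery = 0.3),
    emotion_model = list(
      baseline = c(HG = 0.2, FAO = 0.35, SDLG = 0.3, AD = 0.08),
      effects = list(HG = c(radiation_therapy = 8))),
    seed = 21)
  corp <- generate_corpus(cfg)
  truth <- attr(corp, "truth")
  got <- mined_lift(truth, "radiation_therapy", "HG")
  expect_gt(got$lift, 1)
  oracle <- expected_lift(cfg, "radiation_therapy", "HG")
  expect_gt(oracle, 1)
  expect_lt(abs(got$lift - oracle) / oracle, 0.1)
})

test_that("corpus JSONL round-trips, and tokens records are accepted", {
  cfg <- default_generator_config(n_total = 60, seed = 4)
  corp <- generate_corpus(cfg)
  tf <- withr::local_tempfile(fileext = ".jsonl")
  tt <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, tf, tt)
  back <- read_corpus_jsonl(tf)
  expect_equal(back$id, corp$id)
  expect_equal(back$text, corp$text)
  expect_true(file.exists(tt))
  # token-array records
  tf2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id":"a","channel":"blog","tokens":["cancer","hope"]}'), tf2)
  expect_equal(read_corpus_jsonl(tf2)$text, "cancer hope")
})
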