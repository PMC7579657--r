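# Synthetic corpus generator: channel-tagged posts with known factor
# prevalences and a planted logistic factor->emotion effect model, plus a
# closed-form lift oracle used as ground truth by the tests.

# Default prevalences emulate the study corpus marginals (printed channel
# frequency tables over 321,339 posts); items never printed are set once
# to small realistic values. See the methods vignette.
DEFAULT_FACTOR_PREVALENCE <- c(
  male = 0.1698, female = 0.2086,
  age_under_10 = 0.0269, age_10s = 0.0201, age_20s = 0.0153,
  age_30s = 0.0156, age_40s = 0.0175, age_50s = 0.0179,
  age_60s = 0.0027, age_70s = 0.0020, age_over_80 = 0.0019,
  breast_cancer = 0.0843, colon_cancer = 0.0765, gastric_cancer = 0.0668,
  leukemia = 0.0668, lung_cancer = 0.0605, cervical_cancer = 0.0579,
  liver_cancer = 0.0489, brain_cancer = 0.0441, pancreatic_cancer = 0.0331,
  ovarian_cancer = 0.0307, prostatic_cancer = 0.0234,
  gallbladder_cancer = 0.0116, kidney_cancer = 0.0080,
  thyroid_cancer = 0.0023,
  early_stage = 0.0590, middle_stage = 0.0100, terminal_stage = 0.0200,
  surgery = 0.2115, chemotherapy = 0.1501, radiation_therapy = 0.0650,
  immunotherapy = 0.0600, cam = 0.0465, transplantation = 0.0150,
  acute_survival = 0.4577, extended_survival = 0.0927,
  permanent_survival = 0.0501,
  fatigue_pain_fever = 0.2164, gastrointestinal_problems = 0.0988,
  hair_loss_skin_problems = 0.0812, poor_circulation = 0.0100,
  thrombocytopenia = 0.0050, infection = 0.0200
)

# Planted factor->emotion odds multipliers reflecting the qualitative
# associations reported for the study corpus (treatments, acute survival
# and breast/liver cancer lift hope/gratitude; early stage, GI problems
# and pancreatic/brain cancer lift fear/anxiety; hair loss, surgery and
# fatigue lift sadness; hair loss and acute survival lift anger/denial).
DEFAULT_EMOTION_EFFECTS <- list(
  HG = c(radiation_therapy = 3.0, chemotherapy = 2.2, breast_cancer = 2.0,
         surgery = 1.8, liver_cancer = 1.8, acute_survival = 2.0),
  FAO = c(early_stage = 2.5, gastrointestinal_problems = 2.2,
          chemotherapy = 1.5, fatigue_pain_fever = 1.8,
          pancreatic_cancer = 2.2, brain_cancer = 1.8,
          acute_survival = 1.5),
  SDLG = c(hair_loss_skin_problems = 2.8, surgery = 1.8,
           fatigue_pain_fever = 1.9, male = 1.3, female = 1.3),
  AD = c(hair_loss_skin_problems = 2.0, acute_survival = 1.5,
         male = 1.4, female = 1.3)
)

# Baseline emotion probabilities calibrated (fixed point on the exact
# conditioned marginals, see vignette) so that with the default effects
# the emotion-bearing corpus shows marginals 46.5/45.2/39.4/8.0%.
DEFAULT_EMOTION_BASELINE <- c(HG = 0.160548, FAO = 0.180334,
                              SDLG = 0.168734, AD = 0.034524)

DEFAULT_FILLER_VOCAB <- c(
  "today", "really", "again", "still", "family", "friend", "doctor",
  "hospital", "visit", "news", "reading", "writing", "sharing", "story",
  "everyone", "together", "morning", "evening", "week", "month",
  "thinking", "talking", "question", "answer", "people", "time",
  "day", "experience", "post", "thread"
)

DEFAULT_CHANNEL_SHARES <- c(blog = 0.401, cafe = 0.392,
                            twitter = 0.190, board = 0.017)

#' Configuration of the synthetic corpus generator
#'
#' Describes the generative model: per-channel post counts, independent
#' Bernoulli presence of each factor item, and a logistic emotion model
#' where factor `f` multiplies the odds of emotion group `e` by
#' `effects[[e]][f]`. Posts with no emotion are resampled (the analyzed
#' corpus contains only emotion-bearing posts) unless the `no_emotion`
#' contamination fraction reinstates them; an `ad` contamination fraction
#' plants advertising keywords.
#'
#' @param n_posts named integer vector of post counts per channel
#'   (names among `blog`, `cafe`, `twitter`, `board`).
#' @param factor_prevalence named probability vector over factor items,
#'   or a named list of such vectors keyed by channel.
#' @param emotion_model list with `baseline` (named probabilities in
#'   (0,1) for the four emotion groups) and `effects` (named list per
#'   emotion group of named odds multipliers >= 0 over factor items).
#' @param contamination named vector with fractions `ad` and `no_emotion`
#'   in `[0,1]`.
#' @param filler_vocab non-lexicon tokens used as filler text.
#' @param mean_fillers mean number of filler tokens per post (Poisson).
#' @param seed integer root seed; per-channel streams are derived from it.
#' @param catalog an [item_catalog()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_posts,
                             factor_prevalence,
                             emotion_model,
                             contamination = c(ad = 0, no_emotion = 0),
                             filler_vocab = DEFAULT_FILLER_VOCAB,
                             mean_fillers = 6,
                             seed = NULL,
                             catalog = item_catalog()) {
  n_posts <- round(n_posts)
  if (is.null(names(n_posts)) || !all(names(n_posts) %in% CHANNELS)) {
    stop("n_posts must be named with channels among: ",
         paste(CHANNELS, collapse = ", "))
  }
  if (any(n_posts < 0)) stop("n_posts must be >= 0")

  check_prev <- function(p) {
    if (is.null(names(p)) || !all(names(p) %in% catalog$factor_groups)) {
      stop("factor_prevalence names must be factor items in the catalog")
    }
    if (any(p < 0 | p > 1)) stop("factor prevalences must be in [0, 1]")
    full <- stats::setNames(numeric(length(catalog$factor_groups)),
                            catalog$factor_groups)
    full[names(p)] <- p
    full
  }
  if (is.list(factor_prevalence)) {
    if (!all(names(factor_prevalence) %in% CHANNELS)) {
      stop("per-channel factor_prevalence must be keyed by channel")
    }
    if (!all(names(n_posts) %in% names(factor_prevalence))) {
      stop("per-channel factor_prevalence missing channel(s): ",
           paste(setdiff(names(n_posts), names(factor_prevalence)),
                 collapse = ", "))
    }
    factor_prevalence <- lapply(factor_prevalence, check_prev)
  } else {
    factor_prevalence <- check_prev(factor_prevalence)
  }

  beta <- emotion_model$baseline
  if (!setequal(names(beta), catalog$emotion_groups) ||
      any(beta <= 0 | beta >= 1)) {
    stop("emotion_model$baseline must name all four emotion groups with ",
         "probabilities in (0, 1)")
  }
  effects <- emotion_model$effects
  if (is.null(effects)) effects <- list()
  for (e in names(effects)) {
    if (!e %in% catalog$emotion_groups) stop("unknown emotion group: ", e)
    eff <- effects[[e]]
    if (!all(names(eff) %in% catalog$factor_groups)) {
      stop("effects for ", e, " name unknown factor item(s): ",
           paste(setdiff(names(eff), catalog$factor_groups), collapse = ", "))
    }
    if (any(eff < 0)) stop("odds multipliers must be >= 0")
  }
  contamination <- c(ad = unname(contamination["ad"]),
                     no_emotion = unname(contamination["no_emotion"]))
  contamination[is.na(contamination)] <- 0
  if (any(contamination < 0 | contamination > 1)) {
    stop("contamination fractions must be in [0, 1]")
  }
  structure(
    list(n_posts = n_posts,
         factor_prevalence = factor_prevalence,
         emotion_model = list(baseline = beta[catalog$emotion_groups],
                              effects = effects),
         contamination = contamination,
         filler_vocab = filler_vocab,
         mean_fillers = mean_fillers,
         seed = seed,
         catalog = catalog),
    class = "generator_config"
  )
}

#' Default generator configuration emulating the study corpus
#'
#' Channel shares, factor prevalences and emotion marginals approximate
#' the published marginal structure of the 321,339-post corpus; effects
#' plant the qualitatively reported factor-emotion associations.
#'
#' @param n_total total number of posts across the four channels.
#' @param seed integer root seed.
#' @return object of class `generator_config`.
#' @export
default_generator_config <- function(n_total = 20000, seed = NULL) {
  n <- floor(n_total * DEFAULT_CHANNEL_SHARES)
  n["blog"] <- n["blog"] + (n_total - sum(n))
  generator_config(
    n_posts = n,
    factor_prevalence = DEFAULT_FACTOR_PREVALENCE,
    emotion_model = list(baseline = DEFAULT_EMOTION_BASELINE,
                         effects = DEFAULT_EMOTION_EFFECTS),
    contamination = c(ad = 0, no_emotion = 0),
    seed = seed
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic corpus generator config\n")
  cat("  posts:", paste(sprintf("%s=%d", names(x$n_posts), x$n_posts),
                        collapse = ", "), "\n")
  cat("  contamination: ad =", x$contamination["ad"],
      ", no_emotion =", x$contamination["no_emotion"], "\n")
  cat("  seed:", if (is.null(x$seed)) "unset" else x$seed, "\n")
  invisible(x)
}

# log odds multipliers as a 43 x 4 matrix; multiplier 0 is clamped to a
# large negative log so matrix products stay finite (p becomes 0).
log_effect_matrix <- function(config) {
  catalog <- config$catalog
  m <- matrix(0, length(catalog$factor_groups),
              length(catalog$emotion_groups),
              dimnames = list(catalog$factor_groups, catalog$emotion_groups))
  for (e in names(config$emotion_model$effects)) {
    eff <- config$emotion_model$effects[[e]]
    m[names(eff), e] <- log(pmax(eff, 1e-300))
  }
  m
}

channel_prevalence <- function(config, channel) {
  if (is.list(config$factor_prevalence)) {
    config$factor_prevalence[[channel]]
  } else {
    config$factor_prevalence
  }
}

#' Generate a synthetic corpus
#'
#' For each post, factor items are sampled as independent Bernoulli
#' draws; each emotion group `e` is then Bernoulli with probability
#' `plogis(qlogis(baseline_e) + sum over present factors of
#' log(effect))`. Posts with zero emotions are resampled unless the
#' `no_emotion` contamination fraction requests them; an `ad`
#' contamination fraction adds an advertising keyword. Each planted item
#' is rendered as a lexicon term interleaved with filler tokens; Twitter
#' posts are capped at 140 characters.
#'
#' @param config a [generator_config()].
#' @param lexicon an `emo_lexicon` used to render items as terms;
#'   defaults to the shipped stand-in lexicon.
#' @param seed overrides `config$seed`.
#' @return data.frame with columns `id`, `channel`, `text`, of class
#'   `emo_corpus`, with attributes `truth` (n x 47 0/1 matrix of planted
#'   items — for validation only, never read by the pipeline) and `ad`
#'   (logical vector of planted advertising posts).
#' @export
generate_corpus <- function(config, lexicon = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(lexicon)) {
    lexicon <- read_lexicon(system.file("extdata", "standin_lexicon.tsv",
                                        package = "emomine"))
  }
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  catalog <- config$catalog
  items <- catalog$all_items
  n_emo <- length(catalog$emotion_groups)

  terms_by_item <- lapply(items, terms_for_item, lexicon = lexicon)
  names(terms_by_item) <- items
  cancer_terms <- terms_for_item(lexicon, "cancer_keyword")
  ad_terms <- terms_for_item(lexicon, "ad_keyword")
  if (length(cancer_terms) == 0) {
    stop("lexicon has no cancer_keyword terms; generated posts could not ",
         "pass the topic filter")
  }
  if (config$contamination["ad"] > 0 && length(ad_terms) == 0) {
    stop("ad contamination requested but lexicon has no ad_keyword terms")
  }
  # filler tokens must not collide with lexicon terms
  filler <- setdiff(normalize_term(config$filler_vocab),
                    lexicon$entries$term)
  if (length(filler) == 0) filler <- "filler"

  logeff <- log_effect_matrix(config)
  qb <- stats::qlogis(config$emotion_model$baseline)
  channels <- names(config$n_posts)[config$n_posts > 0]

  set.seed(as.integer(seed))
  channel_seeds <- stats::setNames(sample.int(.Machine$integer.max,
                                              length(CHANNELS)), CHANNELS)

  out <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    n <- config$n_posts[[ch]]
    prev <- channel_prevalence(config, ch)
    set.seed(channel_seeds[[ch]])

    draw <- function(k) {
      F <- matrix(stats::runif(k * length(prev)) < rep(prev, each = k),
                  nrow = k)
      eta <- sweep(F %*% logeff, 2, qb, "+")
      E <- matrix(stats::runif(k * n_emo), nrow = k) < stats::plogis(eta)
      list(F = F, E = E)
    }
    d <- draw(n)
    Fm <- d$F; Em <- d$E
    keep_zero <- stats::runif(n) < config$contamination["no_emotion"]
    # resample full posts (factors and emotions) that drew zero emotions
    for (iter in seq_len(10000)) {
      bad <- which(!keep_zero & rowSums(Em) == 0)
      if (length(bad) == 0) break
      r <- draw(length(bad))
      Fm[bad, ] <- r$F
      Em[bad, ] <- r$E
    }
    if (any(!keep_zero & rowSums(Em) == 0)) {
      stop("could not sample emotion-bearing posts; emotion probabilities ",
           "are degenerate")
    }
    Em[keep_zero, ] <- FALSE
    is_ad <- stats::runif(n) < config$contamination["ad"]

    truth <- cbind(Em, Fm) * 1L
    colnames(truth) <- items
    # sample one rendering term per planted item mention
    hits <- which(truth == 1L, arr.ind = TRUE)
    uncovered <- unique(items[hits[, 2]][
      lengths(terms_by_item[items[hits[, 2]]]) == 0])
    if (length(uncovered) > 0) {
      stop("lexicon has no terms for planted item(s): ",
           paste(uncovered, collapse = ", "))
    }
    hit_terms <- character(nrow(hits))
    for (j in unique(hits[, 2])) {
      rows <- hits[, 2] == j
      hit_terms[rows] <- sample(terms_by_item[[items[j]]], sum(rows),
                                replace = TRUE)
    }
    terms_by_post <- split(hit_terms, factor(hits[, 1], levels = seq_len(n)))

    ids <- sprintf("%s_%05d", ch, seq_len(n))
    base_cancer <- sample(cancer_terms, n, replace = TRUE)
    base_ad <- if (any(is_ad)) sample(ad_terms, n, replace = TRUE) else NULL
    n_fill <- stats::rpois(n, config$mean_fillers)
    text <- character(n)
    for (i in seq_len(n)) {
      toks <- c(base_cancer[i], terms_by_post[[i]])
      if (is_ad[i]) toks <- c(toks, base_ad[i])
      mandatory_len <- sum(nchar(toks, type = "chars")) + length(toks) - 1L
      if (ch == "twitter" && mandatory_len > 140L) {
        stop("generation error: post ", ids[i],
             " cannot satisfy the 140-character limit (",
             mandatory_len, " characters of planted terms)")
      }
      if (n_fill[i] > 0) {
        fills <- sample(filler, n_fill[i], replace = TRUE)
        if (ch == "twitter") {
          budget <- 140L - mandatory_len
          cum <- cumsum(nchar(fills, type = "chars") + 1L)
          fills <- fills[cum <= budget]
        }
        toks <- c(toks, fills)
      }
      text[i] <- paste(sample(toks), collapse = " ")
    }
    corp <- data.frame(id = ids, channel = ch, text = text,
                       stringsAsFactors = FALSE)
    attr(corp, "truth") <- truth
    attr(corp, "ad") <- is_ad
    out[[ci]] <- corp
  }
  corpus <- do.call(rbind, lapply(out, function(x) x[, c("id", "channel", "text")]))
  rownames(corpus) <- NULL
  attr(corpus, "truth") <- do.call(rbind, lapply(out, attr, "truth"))
  attr(corpus, "ad") <- unlist(lapply(out, attr, "ad"), use.names = FALSE)
  class(corpus) <- c("emo_corpus", "data.frame")
  corpus
}

#' Exact lift implied by a generator configuration
#'
#' Computes `P(consequent | all antecedent factors present) /
#' P(consequent)` under the generative model by exact enumeration over
#' the factor configurations that can influence any emotion (all other
#' factors are independent of the emotions and cancel). By default the
#' probabilities are conditioned on the post carrying at least one
#' emotion group, matching the corpus the pipeline actually analyzes
#' (zero-emotion posts are resampled at generation and filtered out
#' downstream).
#'
#' @param config a [generator_config()].
#' @param antecedent character vector of factor items (possibly empty).
#' @param consequent a single emotion group.
#' @param condition_on_emotion condition on >= 1 emotion group present
#'   (the default, matching the analyzed corpus). Set to `FALSE` for the
#'   raw unconditional model.
#' @return the exact lift (a number; 1 under independence).
#' @export
expected_lift <- function(config, antecedent, consequent,
                          condition_on_emotion = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  catalog <- config$catalog
  antecedent <- as.character(antecedent)
  if (!all(antecedent %in% catalog$factor_groups)) {
    stop("antecedent must contain factor items from the catalog")
  }
  if (length(consequent) != 1 || !consequent %in% catalog$emotion_groups) {
    stop("consequent must be a single emotion group")
  }
  logeff <- log_effect_matrix(config)
  active <- sort(unique(c(antecedent,
                          rownames(logeff)[rowSums(logeff != 0) > 0])))
  if (length(active) > 20) {
    stop("more than 20 active factors; exact enumeration refused")
  }
  qb <- stats::qlogis(config$emotion_model$baseline)

  m <- length(active)
  G <- matrix(0L, nrow = 2^m, ncol = m, dimnames = list(NULL, active))
  if (m > 0) {
    for (j in seq_len(m)) {
      G[, j] <- rep(rep(0:1, each = 2^(j - 1)), length.out = 2^m)
    }
  }
  pe_G <- stats::plogis(sweep(G %*% logeff[active, , drop = FALSE], 2, qb, "+"))
  keep_G <- 1 - apply(1 - pe_G, 1, prod)
  ant_mask <- if (length(antecedent) == 0) {
    rep(TRUE, nrow(G))
  } else {
    rowSums(G[, antecedent, drop = FALSE]) == length(antecedent)
  }

  channels <- names(config$n_posts)[config$n_posts > 0]
  w <- config$n_posts[channels] / sum(config$n_posts[channels])
  num_e <- den_e <- num_a <- den_a <- 0
  for (ch in channels) {
    prev <- channel_prevalence(config, ch)[active]
    probs <- rep(1, nrow(G))
    for (j in seq_len(m)) {
      probs <- probs * ifelse(G[, j] == 1L, prev[j], 1 - prev[j])
    }
    pe <- pe_G[, consequent]
    keep <- if (condition_on_emotion) keep_G else rep(1, nrow(G))
    num_e <- num_e + w[[ch]] * sum(probs * pe)
    den_e <- den_e + w[[ch]] * sum(probs * keep)
    num_a <- num_a + w[[ch]] * sum(probs[ant_mask] * pe[ant_mask])
    den_a <- den_a + w[[ch]] * sum(probs[ant_mask] * keep[ant_mask])
  }
  if (den_a == 0 || num_e == 0) {
    stop("antecedent has probability zero or consequent never occurs")
  }
  (num_a / den_a) / (num_e / den_e)
}

#' Exact emotion-group marginals implied by a generator configuration
#'
#' @inheritParams expected_lift
#' @param condition_on_emotion condition on >= 1 emotion group present.
#' @return named numeric vector of `P(e)` for the four emotion groups.
#' @export
expected_emotion_marginals <- function(config, condition_on_emotion = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  catalog <- config$catalog
  logeff <- log_effect_matrix(config)
  active <- rownames(logeff)[rowSums(logeff != 0) > 0]
  if (length(active) > 20) {
    stop("more than 20 active factors; exact enumeration refused")
  }
  qb <- stats::qlogis(config$emotion_model$baseline)
  m <- length(active)
  G <- matrix(0L, nrow = 2^m, ncol = max(m, 1))[, seq_len(m), drop = FALSE]
  colnames(G) <- active
  for (j in seq_len(m)) {
    G[, j] <- rep(rep(0:1, each = 2^(j - 1)), length.out = 2^m)
  }
  pe_G <- stats::plogis(sweep(G %*% logeff[active, , drop = FALSE], 2, qb, "+"))
  keep_G <- if (condition_on_emotion) 1 - apply(1 - pe_G, 1, prod) else rep(1, nrow(G))

  channels <- names(config$n_posts)[config$n_posts > 0]
  w <- config$n_posts[channels] / sum(config$n_posts[channels])
  num <- stats::setNames(numeric(length(catalog$emotion_groups)),
                         catalog$emotion_groups)
  den <- 0
  for (ch in channels) {
    prev <- channel_prevalence(config, ch)[active]
    probs <- rep(1, nrow(G))
    for (j in seq_len(m)) {
      probs <- probs * ifelse(G[, j] == 1L, prev[j], 1 - prev[j])
    }
    num <- num + w[[ch]] * colSums(probs * pe_G)
    den <- den + w[[ch]] * sum(probs * keep_G)
  }
  num / den
}

#' Write a corpus (and optionally its ground truth) as JSONL
#'
#' One JSON object per line with fields `id`, `channel`, `text`. The
#' ground truth (planted items per post) goes to a sibling file that the
#' pipeline never reads.
#'
#' @param corpus an `emo_corpus` or any data.frame with `id`, `channel`,
#'   `text`.
#' @param path output path for the corpus JSONL.
#' @param truth_path optional output path for the ground-truth JSONL.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path, truth_path = NULL) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(id = corpus$id[i], channel = corpus$channel[i],
                          text = corpus$text[i]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  truth <- attr(corpus, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    tl <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(id = corpus$id[i],
                            items = colnames(truth)[truth[i, ] == 1L]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(tl, truth_path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a JSONL corpus
#'
#' Accepts records with either a `text` field or a `tokens` array
#' (joined with spaces).
#'
#' @param path path to a JSONL file.
#' @return data.frame with columns `id`, `channel`, `text`.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  recs <- lapply(readLines(path, encoding = "UTF-8", warn = FALSE),
                 jsonlite::fromJSON)
  recs <- recs[lengths(recs) > 0]
  txt <- vapply(recs, function(r) {
    if (!is.null(r$text)) as.character(r$text)
    else if (!is.null(r$tokens)) paste(unlist(r$tokens), collapse = " ")
    else stop("corpus record lacks both 'text' and 'tokens'")
  }, character(1))
  data.frame(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    channel = vapply(recs, function(r) as.character(r$channel), character(1)),
    text = txt,
    stringsAsFactors = FALSE
  )
}
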