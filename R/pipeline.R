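# End-to-end pipeline: (generate) -> filter -> code -> frequencies ->
# rules -> networks, with a JSON run manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param lexicon path to a lexicon TSV; defaults to the shipped
#'   stand-in lexicon.
#' @param corpus path to an existing JSONL corpus, or `NULL` when a
#'   generator is configured.
#' @param generator a [generator_config()], or a list accepted by it, or
#'   a list with `n_total` for [default_generator_config()]; `NULL` when
#'   reading a corpus from disk.
#' @param min_support Apriori minimum support, in (0, 1].
#' @param min_confidence minimum rule confidence, in (0, 1].
#' @param top_k_rules rules reported per emotion group.
#' @param top_node_fraction fraction of the item universe reported in
#'   the network node tables.
#' @param seed integer seed used for generation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            lexicon = NULL,
                            corpus = NULL,
                            generator = NULL,
                            min_support = 0.01,
                            min_confidence = 0.1,
                            top_k_rules = 5,
                            top_node_fraction = 0.5,
                            seed = NULL) {
  if (is.null(lexicon)) {
    lexicon <- system.file("extdata", "standin_lexicon.tsv",
                           package = "emomine")
  }
  if (is.null(corpus) && is.null(generator)) {
    stop("configuration error: either a corpus path or a generator ",
         "must be provided")
  }
  for (th in c(min_support, min_confidence, top_node_fraction)) {
    if (th <= 0 || th > 1) stop("thresholds must be in (0, 1]")
  }
  if (top_k_rules < 1) stop("top_k_rules must be >= 1")
  if (!is.null(generator) && !inherits(generator, "generator_config")) {
    generator <- if (!is.null(generator$n_total)) {
      default_generator_config(n_total = generator$n_total,
                               seed = generator$seed)
    } else {
      do.call(generator_config, generator)
    }
  }
  structure(list(out_dir = out_dir, lexicon = lexicon, corpus = corpus,
                 generator = generator, min_support = min_support,
                 min_confidence = min_confidence,
                 top_k_rules = top_k_rules,
                 top_node_fraction = top_node_fraction, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file
#'   with fields matching the arguments of [pipeline_config()].
#' @return object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes generate (when configured), filter, code, frequency, rule
#' mining, and network construction, writing every artifact plus a JSON
#' run manifest to `config$out_dir`. Artifacts: `corpus.jsonl` (+
#' `corpus_truth.jsonl`) when generated, `filter_report.json`,
#' `transactions.csv`, `channel_table.csv`, `emotion_frequencies.csv`,
#' `channel_shares.csv`, `rules.csv` / `rules.jsonl`, `top_rules.csv`,
#' and per-stratum `network_<stratum>.graphml`,
#' `network_<stratum>_edges.csv`, `nodes_<stratum>.csv`.
#'
#' @param config a [pipeline_config()] (or a path to one on disk).
#' @param quiet suppress stage-boundary logging.
#' @return (invisibly) list with the in-memory results: `corpus`,
#'   `report`, `transactions`, `channel_table`, `emotion_frequencies`,
#'   `channel_shares`, `frequent`, `rules`, `top_rules`, `networks`,
#'   `top_nodes`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (!quiet) message("[emomine] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- character(0)
  catalog <- item_catalog()
  lexicon <- read_lexicon(config$lexicon, catalog)

  if (!is.null(config$generator)) {
    seed <- if (!is.null(config$seed)) config$seed else config$generator$seed
    if (is.null(seed)) stop("configuration error: generator requires a seed")
    log("generate: ", sum(config$generator$n_posts), " posts (seed ", seed, ")")
    corpus <- generate_corpus(config$generator, lexicon, seed = seed)
    write_corpus_jsonl(corpus, out("corpus.jsonl"), out("corpus_truth.jsonl"))
    paths <- c(paths, out("corpus.jsonl"), out("corpus_truth.jsonl"))
  } else {
    log("read corpus: ", config$corpus)
    corpus <- read_corpus_jsonl(config$corpus)
  }
  log("filter: ", nrow(corpus), " posts in")
  flt <- filter_posts(corpus, lexicon)
  write_filter_report(flt$report, out("filter_report.json"))
  paths <- c(paths, out("filter_report.json"))
  log("filter: ", flt$report$n_selected, " posts selected")

  ts <- code_posts(flt$posts, lexicon)
  write_transactions(ts, out("transactions.csv"))
  paths <- c(paths, out("transactions.csv"))
  log("code: ", ts$n_posts, " x ", length(ts$items), " transaction matrix")

  ctab <- channel_table(ts, catalog = catalog)
  efreq <- emotion_frequencies(ts, catalog)
  shares <- channel_shares(ts)
  utils::write.csv(ctab, out("channel_table.csv"), row.names = FALSE)
  utils::write.csv(efreq, out("emotion_frequencies.csv"), row.names = FALSE)
  utils::write.csv(shares, out("channel_shares.csv"), row.names = FALSE)
  paths <- c(paths, out("channel_table.csv"), out("emotion_frequencies.csv"),
             out("channel_shares.csv"))
  log("frequencies: ", nrow(ctab), " characteristic rows")

  frequent <- apriori(ts, config$min_support)
  rules <- generate_rules(frequent, config$min_confidence, catalog)
  top <- top_rules_by_lift(rules, config$top_k_rules)
  write_rules(rules, out("rules.csv"), out("rules.jsonl"))
  utils::write.csv(
    data.frame(antecedent = top$antecedent_str, consequent = top$consequent,
               support = sprintf("%.3f", round_half_up(top$support, 3)),
               confidence = sprintf("%.3f", round_half_up(top$confidence, 3)),
               lift = sprintf("%.3f", round_half_up(top$lift, 3))),
    out("top_rules.csv"), row.names = FALSE, quote = FALSE)
  paths <- c(paths, out("rules.csv"), out("rules.jsonl"), out("top_rules.csv"))
  log("rules: ", nrow(frequent), " frequent itemsets, ", nrow(rules),
      " rules (min_support ", config$min_support, ", min_confidence ",
      config$min_confidence, ")")

  networks <- list()
  topn <- list()
  for (st in c("longform", "twitter")) {
    net <- build_network(ts, st)
    networks[[st]] <- net
    topn[[st]] <- top_nodes(net, config$top_node_fraction)
    if (nrow(net$edges) > 0) {
      write_graphml(net, out(paste0("network_", st, ".graphml")))
      paths <- c(paths, out(paste0("network_", st, ".graphml")))
    }
    write_edge_list(net, out(paste0("network_", st, "_edges.csv")))
    utils::write.csv(topn[[st]], out(paste0("nodes_", st, ".csv")),
                     row.names = FALSE)
    paths <- c(paths, out(paste0("network_", st, "_edges.csv")),
               out(paste0("nodes_", st, ".csv")))
    log("network (", st, "): ", nrow(net$nodes), " nodes, ",
        nrow(net$edges), " edges over ", net$n_posts, " posts")
  }

  manifest <- list(
    seed = config$seed,
    thresholds = list(min_support = config$min_support,
                      min_confidence = config$min_confidence,
                      top_k_rules = config$top_k_rules,
                      top_node_fraction = config$top_node_fraction),
    funnel = unclass(flt$report),
    outputs = stats::setNames(
      as.list(c(nrow(ctab) + nrow(efreq) + nrow(shares), ts$n_posts,
                nrow(rules), nrow(top),
                vapply(networks, function(n) nrow(n$edges), numeric(1)))),
      c("frequency_rows", "transactions", "rules", "top_rules",
        "edges_longform", "edges_twitter"))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  paths <- c(paths, out("manifest.json"))
  log("done: ", length(paths), " artifacts in ", config$out_dir)

  invisible(list(corpus = corpus, report = flt$report, transactions = ts,
                 channel_table = ctab, emotion_frequencies = efreq,
                 channel_shares = shares, frequent = frequent,
                 rules = rules, top_rules = top, networks = networks,
                 top_nodes = topn, manifest = manifest, paths = paths))
}
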