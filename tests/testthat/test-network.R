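ts47 <- function(rows, channel) {
  m <- matrix(0L, length(rows), 47,
              dimnames = list(NULL, item_catalog()$all_items))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  transaction_set(m, channel = channel)
}

test_that("a single post yields a triangle with unit weights", {
  ts <- ts47(list(c("HG", "surgery", "male")), "blog")
  net <- build_network(ts, "longform")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(net$nodes$degree, c(2L, 2L, 2L))
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$weight, c(1L, 1L, 1L))
})

test_that("edges count co-mention posts; absent pairs have no edge", {
  ts <- ts47(list(c("HG", "surgery"), c("HG", "male")), "cafe")
  net <- build_network(ts, "longform")
  hg <- net$nodes[net$nodes$item == "HG", ]
  expect_equal(hg$degree, 2L)
  expect_equal(hg$frequency, 2L)
  keys <- paste(net$edges$item_a, net$edges$item_b)
  expect_length(keys, 2)
  expect_false(any(grepl("surgery", keys) & grepl("male", keys)))
  expect_true(all(net$edges$weight == 1L))
})

test_that("network matches the naive pair counter on random corpora", {
  set.seed(83)
  for (trial in 1:5) {
    items <- sample(item_catalog()$all_items, 8)
    mat <- random_transactions(60, items)
    full <- matrix(0L, 60, 47,
                   dimnames = list(NULL, item_catalog()$all_items))
    full[, items] <- mat
    ts <- transaction_set(full, channel = rep("blog", 60))
    net <- build_network(ts, "longform")
    w <- naive_pair_counts(full)
    for (i in seq_len(nrow(net$edges))) {
      expect_equal(net$edges$weight[i],
                   w[net$edges$item_a[i], net$edges$item_b[i]])
    }
    # conservation: sum of weights = sum over posts of choose(m_p, 2)
    expect_equal(sum(net$edges$weight),
                 sum(choose(rowSums(full), 2)))
    # weight(a,b) <= min(freq a, freq b)
    freq <- stats::setNames(net$nodes$frequency, net$nodes$item)
    expect_true(all(net$edges$weight <=
                      pmin(freq[net$edges$item_a], freq[net$edges$item_b])))
  }
})

test_that("strata partition the corpus and add up to corpus marginals", {
  cfg <- default_generator_config(n_total = 1200, seed = 19)
  lex <- standin_lexicon()
  ts <- code_posts(filter_posts(generate_corpus(cfg, lex), lex)$posts, lex)
  long <- build_network(ts, "longform")
  tw <- build_network(ts, "twitter")
  expect_equal(long$n_posts + tw$n_posts, ts$n_posts)
  freq_of <- function(net) {
    stats::setNames(net$nodes$frequency, net$nodes$item)
  }
  fl <- freq_of(long); ft <- freq_of(tw)
  all_items <- union(names(fl), names(ft))
  combined <- stats::setNames(numeric(length(all_items)), all_items)
  combined[names(fl)] <- fl
  combined[names(ft)] <- combined[names(ft)] + ft
  marginal <- colSums(ts$matrix)[all_items]
  expect_equal(unname(combined[all_items]), unname(marginal))
})

test_that("shuffling post order leaves the network unchanged", {
  set.seed(97)
  mat <- random_transactions(80, sample(item_catalog()$all_items, 6))
  full <- matrix(0L, 80, 47, dimnames = list(NULL, item_catalog()$all_items))
  full[, colnames(mat)] <- mat
  ts1 <- transaction_set(full, channel = rep("board", 80))
  perm <- sample(80)
  ts2 <- transaction_set(full[perm, ], channel = rep("board", 80))
  n1 <- build_network(ts1, "longform")
  n2 <- build_network(ts2, "longform")
  expect_equal(n1$nodes, n2$nodes)
  expect_equal(n1$edges, n2$edges)
})

test_that("unknown channels are rejected", {
  m <- matrix(1L, 1, 47, dimnames = list(NULL, item_catalog()$all_items))
  ts <- transaction_set(m, channel = "myspace")
  expect_error(build_network(ts, "longform"), "unknown channel")
})

test_that("top_nodes returns ceil(fraction x 47) ranked nodes", {
  set.seed(103)
  mat <- random_transactions(300, item_catalog()$all_items,
                             p = stats::runif(47, 0.2, 0.8))
  ts <- transaction_set(mat, channel = rep("blog", 300))
  net <- build_network(ts, "longform")
  top <- top_nodes(net, 0.5)
  expect_equal(nrow(top), 24)   # ceiling(0.5 * 47)
  allnodes <- top_nodes(net, 1.0)
  expect_equal(nrow(allnodes), nrow(net$nodes))
  # ordering agrees with a direct re-sort
  nd <- net$nodes[order(-net$nodes$frequency, -net$nodes$degree,
                        net$nodes$item), ]
  expect_equal(top$item, utils::head(nd$item, 24))
  # percent uses the stratum post count as denominator
  expect_equal(top$percent,
               round_half_up(top$frequency / net$n_posts * 100, 1))
  expect_error(top_nodes(net, 0), "fraction")
})

test_that("top_edges ranks by weight and saturates at the edge count", {
  ts <- ts47(list(c("HG", "surgery", "male"),
                  c("HG", "surgery"),
                  c("HG", "surgery"),
                  c("HG", "male")), "blog")
  net <- build_network(ts, "longform")
  top2 <- top_edges(net, 2)
  expect_equal(top2$weight, c(3L, 2L))
  expect_equal(top2$item_a[1], "HG")
  expect_equal(top2$item_b[1], "surgery")
  expect_equal(nrow(top_edges(net, 100)), nrow(net$edges))
})

test_that("GraphML export round-trips through igraph", {
  ts <- ts47(list(c("HG", "surgery", "male"), c("HG", "male")), "blog")
  net <- build_network(ts, "longform")
  gf <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gf)
  g <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(igraph::E(g)$weight), c(1, 1, 2))
  expect_setequal(igraph::V(g)$frequency, net$nodes$frequency)
})
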