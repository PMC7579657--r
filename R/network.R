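# Co-occurrence networks over the analysis items, stratified by post
# length (long-form channels vs Twitter).

#' Build a co-occurrence network for one channel stratum
#'
#' Posts are stratified by length: `longform` pools internet blogs,
#' online cafés, and message boards (long posts), `twitter` holds the
#' 140-character channel. Every unordered pair of items present in a
#' post contributes one post to that edge's weight; a node's frequency
#' is the number of stratum posts mentioning the item, and its degree
#' the number of distinct co-occurring items. Items never mentioned in
#' the stratum are omitted.
#'
#' @param transactions a `transaction_set`.
#' @param stratum `"longform"` or `"twitter"`.
#' @return object of class `cooccurrence_network`: list with `stratum`,
#'   `nodes` (data.frame `item`, `frequency`, `degree`), `edges`
#'   (data.frame `item_a`, `item_b`, `weight`), `n_posts` (posts in the
#'   stratum) and `n_items_universe` (size of the item catalog).
#' @export
build_network <- function(transactions, stratum = c("longform", "twitter")) {
  stratum <- match.arg(stratum)
  unknown <- setdiff(unique(transactions$channel), CHANNELS)
  if (length(unknown) > 0) {
    stop("unknown channel(s) in transactions: ",
         paste(unknown, collapse = ", "))
  }
  chans <- if (stratum == "longform") LONGFORM_CHANNELS else "twitter"
  rows <- transactions$channel %in% chans
  M <- transactions$matrix[rows, , drop = FALSE] > 0
  W <- crossprod(M * 1L)
  freq <- diag(W)
  present <- freq > 0
  A <- W > 0
  diag(A) <- FALSE
  degree <- rowSums(A)

  nodes <- data.frame(item = colnames(W)[present],
                      frequency = as.integer(freq[present]),
                      degree = as.integer(degree[present]),
                      stringsAsFactors = FALSE, row.names = NULL)
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(item_a = rownames(W)[ut[, 1]],
                      item_b = colnames(W)[ut[, 2]],
                      weight = as.integer(W[ut]),
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[order(edges$item_a, edges$item_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(stratum = stratum, nodes = nodes, edges = edges,
                 n_posts = sum(rows),
                 n_items_universe = ncol(transactions$matrix)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network (%s): %d posts, %d nodes, %d edges\n",
              x$stratum, x$n_posts, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Top nodes of a co-occurrence network
#'
#' Ranks nodes by frequency (ties: degree, then item identifier) and
#' returns the top `ceiling(fraction * item universe)` nodes with their
#' frequency, percentage of stratum posts, and degree — e.g. the top 24
#' of 47 items at the default 50%.
#'
#' @param network a `cooccurrence_network`.
#' @param fraction fraction of the item universe to return, in (0, 1].
#' @return data.frame `item`, `frequency`, `percent`, `degree`.
#' @export
top_nodes <- function(network, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  nd <- network$nodes
  if (nrow(nd) == 0) {
    return(data.frame(item = character(0), frequency = integer(0),
                      percent = numeric(0), degree = integer(0),
                      stringsAsFactors = FALSE))
  }
  n_top <- ceiling(fraction * network$n_items_universe)
  nd <- nd[order(-nd$frequency, -nd$degree, nd$item), , drop = FALSE]
  nd <- utils::head(nd, n_top)
  data.frame(item = nd$item, frequency = nd$frequency,
             percent = round_half_up(nd$frequency / network$n_posts * 100, 1),
             degree = nd$degree, stringsAsFactors = FALSE, row.names = NULL)
}

#' Heaviest edges of a co-occurrence network
#'
#' @param network a `cooccurrence_network`.
#' @param k number of edges to return (all edges when `k` exceeds the
#'   edge count).
#' @return data.frame `item_a`, `item_b`, `weight`, by weight descending
#'   (ties broken by item identifiers).
#' @export
top_edges <- function(network, k) {
  ed <- network$edges
  ed <- ed[order(-ed$weight, ed$item_a, ed$item_b), , drop = FALSE]
  rownames(ed) <- NULL
  utils::head(ed, k)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' @param network a `cooccurrence_network`.
#' @return an undirected `igraph` graph with node attributes `frequency`
#'   and `degree` and edge attribute `weight`.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Export a network as GraphML / edge-list CSV
#'
#' @param network a `cooccurrence_network`.
#' @param path output path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
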