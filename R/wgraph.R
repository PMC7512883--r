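#' Construct a weighted undirected graph
#'
#' `wgraph()` builds the package's central data structure: a simple undirected
#' graph with strictly positive edge weights.  Edges are stored canonically
#' (each pair oriented so `from < to`, rows sorted lexicographically), so two
#' graphs with the same nodes and edges compare `identical()`.
#'
#' Invariants enforced at construction: no self-loops, no parallel edges,
#' every weight finite and `> 0`, every endpoint a member of the node set.
#' Node labels are opaque strings; numeric labels are kept as strings so that
#' identities are stable across file formats.
#'
#' @param edges a data frame (or 3-column matrix) whose first three columns
#'   are interpreted as `from`, `to`, `weight`.  May have zero rows.
#' @param nodes optional character vector of node labels; the node set is the
#'   union of `nodes` and all edge endpoints, which permits isolated nodes.
#' @return An object of class `wgraph`: a list with elements `nodes`
#'   (sorted character vector) and `edges` (data frame `from`, `to`,
#'   `weight`).
#' @examples
#' g <- wgraph(data.frame(from = c("A", "B"), to = c("C", "C"),
#'                        weight = c(1, 2)))
#' g
#' @export
wgraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3 && nrow(edges) > 0) {
    stop_arg("`edges` needs columns from, to, weight")
  }
  if (nrow(edges) == 0) {
    ed <- data.frame(from = character(), to = character(),
                     weight = numeric(), stringsAsFactors = FALSE)
  } else {
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
    weight <- as.numeric(edges[[3]])
    if (anyNA(from) || anyNA(to)) stop_arg("edge endpoints contain NA")
    if (anyNA(weight) || any(!is.finite(weight))) {
      stop_arg("edge weights must be finite numbers")
    }
    if (any(weight <= 0)) stop_arg("edge weights must be > 0")
    if (any(from == to)) stop_arg("self-loops are not allowed")
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    key <- paste(from, to, sep = "")
    if (anyDuplicated(key)) stop_arg("duplicate edges are not allowed")
    ord <- order(from, to, method = "radix")
    ed <- data.frame(from = from[ord], to = to[ord], weight = weight[ord],
                     stringsAsFactors = FALSE)
  }
  all_nodes <- sort(unique(c(as.character(nodes %||% character()),
                             ed$from, ed$to)), method = "radix")
  structure(list(nodes = all_nodes, edges = ed), class = "wgraph")
}

#' @export
print.wgraph <- function(x, ...) {
  cat(sprintf("wgraph: %d nodes, %d edges, total weight %g\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  if (nrow(x$edges)) {
    utils::head(x$edges, 6L) -> h
    print(h, row.names = FALSE)
    if (nrow(x$edges) > 6L) cat(sprintf("... %d more edges\n", nrow(x$edges) - 6L))
  }
  invisible(x)
}

is_wgraph <- function(x) inherits(x, "wgraph")

assert_wgraph <- function(g) {
  if (!is_wgraph(g)) stop_arg("expected a `wgraph` object")
  invisible(g)
}

#' Basic graph sizes
#'
#' @param g a [wgraph()].
#' @return `n_nodes()`: the number of nodes; `n_edges()`: the number of
#'   edges; `total_weight()`: the sum of all edge weights.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
total_weight <- function(g) sum(g$edges$weight)

#' Test for the presence of an edge
#'
#' @param graph a [wgraph()] object.
#' @param x,y node labels.
#' @return `TRUE` if the unordered pair `{x, y}` is an edge of `graph`.
#' @export
has_edge <- function(graph, x, y) {
  assert_wgraph(graph)
  edge_key(x, y) %in% edge_key(graph$edges$from, graph$edges$to)
}

#' Per-node degree, strength and neighbourhoods
#'
#' Computes for every node x the degree k(x) = |Gamma(x)|, the strength
#' s(x) = sum of weights on incident edges, and the neighbour set Gamma(x).
#' Isolated nodes get degree 0, strength 0 and an empty neighbourhood.
#'
#' @param graph a [wgraph()] object.
#' @return An object of class `node_stats`: list with named vectors `degree`
#'   and `strength` and a named list `neighbors`, all indexed by node label.
#' @examples
#' g <- toy_g0()
#' node_stats(g)$strength[["C"]]   # 1 + 2 = 3
#' @export
node_stats <- function(graph) {
  assert_wgraph(graph)
  adj <- adjacency(graph)
  degree <- lengths(adj)
  strength <- vapply(adj, sum, numeric(1))
  structure(list(degree = degree, strength = strength,
                 neighbors = lapply(adj, names)),
            class = "node_stats")
}

#' @export
print.node_stats <- function(x, ...) {
  cat(sprintf("node_stats over %d nodes (sum k = %d, sum s = %g)\n",
              length(x$degree), sum(x$degree), sum(x$strength)))
  invisible(x)
}

# Adjacency as a named list: adj[[node]] is a named numeric vector of
# incident edge weights, names = neighbour labels.  Every node present.
adjacency <- function(g) {
  nodes <- g$nodes
  ends_a <- c(g$edges$from, g$edges$to)
  ends_b <- c(g$edges$to, g$edges$from)
  w2 <- rep(g$edges$weight, 2L)
  idx <- split(seq_along(ends_a), factor(ends_a, levels = nodes))
  lapply(idx, function(i) stats::setNames(w2[i], ends_b[i]))
}

# Strength vector only (cheaper than full node_stats when neighbours unused).
strength_vector <- function(g) {
  s <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    agg <- tapply(c(g$edges$weight, g$edges$weight),
                  c(g$edges$from, g$edges$to), sum)
    s[names(agg)] <- as.numeric(agg)
  }
  s
}

degree_vector <- function(g) {
  k <- stats::setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    tab <- table(c(g$edges$from, g$edges$to))
    k[names(tab)] <- as.integer(tab)
  }
  k
}

# Full invariant check; used by tests and after every null-model operation.
validate_wgraph <- function(g) {
  assert_wgraph(g)
  ed <- g$edges
  stopifnot(
    !any(ed$from == ed$to),
    all(ed$weight > 0),
    all(is.finite(ed$weight)),
    all(ed$from < ed$to),
    !anyDuplicated(edge_key(ed$from, ed$to)),
    all(c(ed$from, ed$to) %in% g$nodes),
    !anyDuplicated(g$nodes)
  )
  invisible(g)
}
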