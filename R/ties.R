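#' Partition edges into strong and weak ties
#'
#' Sorts all edges by weight in descending order and designates the first
#' half as strong ties and the rest as weak ties.  With an odd number of
#' edges the strong half gets the extra edge.  Edges whose weight sits on
#' the boundary are assigned uniformly at random (seeded), so repeated
#' experiments sample a straddling weight class fairly rather than by
#' storage order.
#'
#' @param graph a [wgraph()] with at least 2 edges.
#' @param rng_seed integer seed for boundary tie-breaking.
#' @return A `tie_partition`: list with edge data frames `strong` and
#'   `weak`, the boundary cut value `threshold_weight` (the smallest strong
#'   weight), and `seed`.
#' @examples
#' g <- toy_g0()
#' partition_strong_weak(g, rng_seed = 1)
#' @export
partition_strong_weak <- function(graph, rng_seed) {
  assert_wgraph(graph)
  m <- n_edges(graph)
  if (m < 2) stop_arg("need at least 2 edges to partition")
  tie_break <- withr::with_seed(rng_seed, sample.int(m))
  ord <- order(-graph$edges$weight, tie_break, method = "radix")
  n_strong <- ceiling(m / 2)
  strong_idx <- sort(ord[seq_len(n_strong)])
  weak_idx <- sort(ord[-seq_len(n_strong)])
  strong <- graph$edges[strong_idx, , drop = FALSE]
  weak <- graph$edges[weak_idx, , drop = FALSE]
  rownames(strong) <- NULL; rownames(weak) <- NULL
  structure(list(strong = strong, weak = weak,
                 threshold_weight = min(strong$weight),
                 seed = as.integer(rng_seed)),
            class = "tie_partition")
}

#' @export
print.tie_partition <- function(x, ...) {
  cat(sprintf("tie_partition: %d strong / %d weak (cut at weight %g)\n",
              nrow(x$strong), nrow(x$weak), x$threshold_weight))
  invisible(x)
}

#' Draw a uniformly random half of the edges
#'
#' Control subset for the strong/weak tie experiments: a uniformly random
#' subset of `floor(|E| / 2)` edges, seed-deterministic.
#'
#' @inheritParams partition_strong_weak
#' @return An edge data frame (`from`, `to`, `weight`).
#' @export
random_half <- function(graph, rng_seed) {
  assert_wgraph(graph)
  m <- n_edges(graph)
  if (m < 2) stop_arg("need at least 2 edges")
  idx <- withr::with_seed(rng_seed, sort(sample.int(m, floor(m / 2))))
  out <- graph$edges[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset-restricted 1k randomisation
#'
#' Identical contract to [rewire_1k()], except both edges of every double
#' swap are drawn from (the current images of) `subset`.  A swap replaces
#' two subset edges with two new edges which inherit subset membership, so
#' the scrambled subset stays closed under rewiring while every edge outside
#' the subset is left bit-identical.  Used to scramble only the strong ties,
#' only the weak ties, or a random half.
#'
#' @inheritParams rewire_1k
#' @param subset edges to scramble: an edge data frame (`from`, `to`, ...)
#'   or a character vector of node labels of length 2k.  Must be a subset of
#'   the graph's edges, of size at least 2.
#' @return A `null_report`.
#' @export
rewire_1k_subset <- function(graph, subset, n_swaps = NULL, rng_seed) {
  assert_wgraph(graph)
  keys <- subset_keys(subset)
  all_keys <- edge_key(graph$edges$from, graph$edges$to)
  idx <- match(keys, all_keys)
  if (anyNA(idx)) stop_arg("subset contains pairs that are not edges of the graph")
  if (anyDuplicated(idx)) stop_arg("subset contains duplicate edges")
  if (length(idx) < 2) stop_arg("subset must contain at least 2 edges")
  if (is.null(n_swaps)) n_swaps <- 2L * length(idx)
  rewire_1k_engine(graph, idx, n_swaps, rng_seed, kind = "ONE_K")
}

subset_keys <- function(subset) {
  if (is.data.frame(subset)) {
    edge_key(as.character(subset[[1]]), as.character(subset[[2]]))
  } else if (is.character(subset) && length(subset) %% 2 == 0) {
    m <- matrix(subset, ncol = 2, byrow = TRUE)
    edge_key(m[, 1], m[, 2])
  } else {
    stop_arg("subset must be an edge data frame or an even-length label vector")
  }
}
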