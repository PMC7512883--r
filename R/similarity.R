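#' Local similarity indices for link prediction
#'
#' Six neighbourhood-based similarity scores for a node pair (x, y), computed
#' on the supplied graph (during evaluation this is the training graph, so
#' probe edges are invisible to neighbourhoods, degrees, strengths and
#' weights).  With Z = Gamma(x) intersect Gamma(y) the common-neighbour set:
#'
#' * `CN`:  |Z|
#' * `AA`:  sum over z of 1 / log k(z)
#' * `RA`:  sum over z of 1 / k(z)
#' * `WCN`: sum over z of w(x,z)^alpha + w(z,y)^alpha
#' * `WAA`: sum over z of (w(x,z)^alpha + w(z,y)^alpha) / log(1 + s(z))
#' * `WRA`: sum over z of (w(x,z)^alpha + w(z,y)^alpha) / s(z)
#'
#' `alpha` tunes the role of the weights: `alpha = 0` reduces `WCN` to
#' exactly `2 * CN`; positive alpha amplifies heavy edges, negative alpha
#' amplifies weak ones.  Logarithms are natural; the base only rescales AA
#' (and WAA) by a constant factor, leaving all rankings, AUC and precision
#' unchanged.  An empty common-neighbour set scores 0 for every index.
#'
#' A common neighbour z always has k(z) >= 2 (it is adjacent to both x and
#' y in the graph being scored), so `1 / log k(z)` never divides by zero;
#' this is asserted rather than special-cased.
#'
#' @param graph a [wgraph()]; scores are computed against this graph.
#' @param x,y distinct node labels present in `graph`.
#' @param index one of `"CN"`, `"AA"`, `"RA"`, `"WCN"`, `"WAA"`, `"WRA"`.
#' @param alpha weight exponent; ignored by the unweighted indices.
#' @return A single non-negative numeric score.
#' @examples
#' g <- toy_g0()
#' score_pair(g, "A", "B", "CN")              # 2
#' score_pair(g, "A", "B", "WCN", alpha = 1)  # 7
#' score_pair(g, "A", "B", "WRA", alpha = 1)  # 2
#' @export
score_pair <- function(graph, x, y, index, alpha = 1) {
  assert_wgraph(graph)
  index <- match_index(index)
  x <- as.character(x); y <- as.character(y)
  if (identical(x, y)) stop_arg("x and y must be distinct")
  if (!x %in% graph$nodes) stop_arg("node not in graph: ", x)
  if (!y %in% graph$nodes) stop_arg("node not in graph: ", y)
  ctx <- score_context(graph)
  score_pairs_ctx(ctx, data.frame(from = x, to = y), index, alpha)
}

#' Score a batch of candidate pairs
#'
#' Batched form of [score_pair()].  Pairs are unordered: `(B, A)` and
#' `(A, B)` are the same key and appear once in the result.
#'
#' @param graph a [wgraph()].
#' @param pairs a two-column data frame or matrix of node labels.
#' @param index,alpha as in [score_pair()].
#' @return A `score_table`: data frame with columns `node_x`, `node_y`
#'   (canonically ordered), `score`, and attributes `index` and `alpha`.
#' @export
score_candidates <- function(graph, pairs, index, alpha = 1) {
  assert_wgraph(graph)
  index <- match_index(index)
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) {
    out <- data.frame(node_x = character(), node_y = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    return(as_score_table(out, index, alpha))
  }
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  if (any(a == b)) stop_arg("pairs must join distinct nodes")
  missing <- setdiff(unique(c(a, b)), graph$nodes)
  if (length(missing)) stop_arg("node not in graph: ", missing[1])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(paste(a, b, sep = ""))
  df <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  ctx <- score_context(graph)
  s <- score_pairs_ctx(ctx, df, index, alpha)
  out <- data.frame(node_x = df$from, node_y = df$to, score = s,
                    stringsAsFactors = FALSE)
  as_score_table(out, index, alpha)
}

as_score_table <- function(df, index, alpha) {
  attr(df, "index") <- index
  attr(df, "alpha") <- alpha
  class(df) <- c("score_table", "data.frame")
  df
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d pairs, index %s (alpha = %g)\n",
              nrow(x), attr(x, "index"), attr(x, "alpha")))
  print(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  invisible(x)
}

index_names <- c("CN", "AA", "RA", "WCN", "WAA", "WRA")

match_index <- function(index) {
  if (!is.character(index) || length(index) != 1 || !index %in% index_names) {
    stop_arg("index must be one of ", paste(index_names, collapse = ", "))
  }
  index
}

# Precomputed scoring context: adjacency, degree, strength on one graph.
score_context <- function(graph) {
  adj <- adjacency(graph)
  list(adj = adj,
       degree = lengths(adj),
       strength = vapply(adj, sum, numeric(1)))
}

# Per-pair profile of the common neighbourhood: everything any of the six
# indices needs, extracted once so that sweeps over (index, alpha) reuse it.
pair_profiles <- function(ctx, pairs) {
  lapply(seq_len(nrow(pairs)), function(i) {
    wx <- ctx$adj[[pairs$from[i]]]
    wy <- ctx$adj[[pairs$to[i]]]
    z <- intersect(names(wx), names(wy))
    list(wxz = unname(wx[z]), wzy = unname(wy[z]),
         kz = unname(ctx$degree[z]), sz = unname(ctx$strength[z]))
  })
}

profile_score <- function(p, index, alpha) {
  if (!length(p$kz)) return(0)
  switch(index,
    CN = length(p$kz),
    AA = { stopifnot(all(p$kz >= 2)); sum(1 / log(p$kz)) },
    RA = sum(1 / p$kz),
    WCN = sum(p$wxz^alpha + p$wzy^alpha),
    WAA = sum((p$wxz^alpha + p$wzy^alpha) / log(1 + p$sz)),
    WRA = sum((p$wxz^alpha + p$wzy^alpha) / p$sz)
  )
}

score_pairs_ctx <- function(ctx, pairs, index, alpha) {
  profiles <- pair_profiles(ctx, pairs)
  vapply(profiles, profile_score, numeric(1), index = index, alpha = alpha)
}
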