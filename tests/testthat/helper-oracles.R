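# Shared test helpers: independent oracles and small graph builders.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact graph comparison (graphs are stored canonically).
graph_equal <- function(a, b) {
  identical(a$nodes, b$nodes) && identical(a$edges, b$edges)
}

# Erdos-Renyi G(n, m) weighted graph, independent of the package generator.
gnm_graph <- function(n, m, seed, weights = NULL) {
  withr::with_seed(seed, {
    nodes <- sprintf("v%03d", seq_len(n))
    pairs <- utils::combn(nodes, 2)
    stopifnot(m <= ncol(pairs))
    idx <- sample(ncol(pairs), m)
    w <- weights %||% sample(1:9, m, replace = TRUE)
    wgraph(data.frame(from = pairs[1, idx], to = pairs[2, idx], weight = w,
                      stringsAsFactors = FALSE))
  })
}

# Brute-force similarity oracle: enumerates every node as a potential common
# neighbour, reading adjacency, degree and strength straight off the edge
# table.  Deliberately shares no code with the package's scorer.
brute_score <- function(g, x, y, index, alpha = 1) {
  ed <- g$edges
  w_of <- function(u, v) {
    i <- (ed$from == u & ed$to == v) | (ed$from == v & ed$to == u)
    if (any(i)) ed$weight[i] else NA_real_
  }
  deg_of <- function(u) sum(ed$from == u | ed$to == u)
  str_of <- function(u) sum(ed$weight[ed$from == u | ed$to == u])
  total <- 0
  for (z in g$nodes) {
    if (z == x || z == y) next
    wxz <- w_of(x, z); wzy <- w_of(z, y)
    if (is.na(wxz) || is.na(wzy)) next
    total <- total + switch(index,
      CN = 1,
      AA = 1 / log(deg_of(z)),
      RA = 1 / deg_of(z),
      WCN = wxz^alpha + wzy^alpha,
      WAA = (wxz^alpha + wzy^alpha) / log(1 + str_of(z)),
      WRA = (wxz^alpha + wzy^alpha) / str_of(z))
  }
  total
}

# Rank-sum AUC oracle: Mann-Whitney U via midranks, U / (n1 n2).
auc_rank_oracle <- function(probe, nonedge) {
  r <- rank(c(probe, nonedge))
  n1 <- length(probe); n2 <- length(nonedge)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Scan seeds until a stochastic single-step operation reproduces `expected`.
find_seed <- function(fn, expected, max_seed = 400L) {
  for (s in seq_len(max_seed)) {
    out <- tryCatch(suppressWarnings(fn(s)), error = function(e) NULL)
    if (!is.null(out) && graph_equal(out, expected)) return(s)
  }
  NA_integer_
}

degree_multiset <- function(g) sort(unname(wnetnull:::degree_vector(g)))
weight_multiset <- function(g) sort(g$edges$weight)
strengths_of <- function(g) wnetnull:::strength_vector(g)
edge_keys_of <- function(g) wnetnull:::edge_key(g$edges$from, g$edges$to)
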