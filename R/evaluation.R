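#' Default grid of weight exponents
#'
#' The exponent grid swept by [run_sweep()]: -2 to 2 in steps of 0.25
#' (which contains -0.5, the region where weak-tie amplification typically
#' peaks on heavy-tailed networks).
#'
#' @return A numeric vector.
#' @export
default_alpha_grid <- function() seq(-2, 2, by = 0.25)

#' Split edges into training, probe and sampled non-edges
#'
#' Standard link-prediction protocol: a uniformly random
#' `round(test_fraction * |pool|)` edges (round half up, minimum 1) become
#' the probe set E^T, everything else remains training E^P, and `|E^T|`
#' distinct non-adjacent node pairs are sampled as the non-edge set E^N.
#' When `restrict_to` is given, the probe is drawn only from that subset
#' (e.g. the strong ties) while the training set still contains all
#' remaining edges of the graph.
#'
#' @param graph a [wgraph()].
#' @param test_fraction fraction of the pool hidden as probe, in (0, 1);
#'   default 0.1 (a 10/90 split).
#' @param restrict_to optional edge subset (data frame) to draw the probe
#'   from.
#' @param rng_seed integer seed.
#' @return A `link_split`: list with edge data frames `training` and
#'   `probe`, a pair data frame `nonedges`, and `seed`.  Errors when the
#'   graph is too dense to supply `|E^T|` non-edges.
#' @export
split_edges <- function(graph, test_fraction = 0.1, restrict_to = NULL,
                        rng_seed) {
  assert_wgraph(graph)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop_arg("test_fraction must be in (0, 1)")
  }
  m <- n_edges(graph)
  if (m < 2) stop_arg("need at least 2 edges to split")
  all_keys <- edge_key(graph$edges$from, graph$edges$to)
  if (is.null(restrict_to)) {
    pool <- seq_len(m)
  } else {
    pool <- match(subset_keys(restrict_to), all_keys)
    if (anyNA(pool)) stop_arg("restrict_to contains pairs that are not edges")
  }
  n_test <- max(1L, as.integer(floor(test_fraction * length(pool) + 0.5)))
  if (n_test >= length(pool)) stop_arg("test fraction leaves no training edges in pool")
  n <- length(graph$nodes)
  n_nonedges_avail <- n * (n - 1) / 2 - m
  if (n_nonedges_avail < n_test) {
    stop_arg("graph too dense: only ", n_nonedges_avail,
             " non-edges available, need ", n_test)
  }
  withr::with_seed(rng_seed, {
    probe_idx <- sort(pool[sample.int(length(pool), n_test)])
    nonedges <- sample_nonedges(graph, n_test)
  })
  probe <- graph$edges[probe_idx, , drop = FALSE]
  training <- graph$edges[-probe_idx, , drop = FALSE]
  rownames(probe) <- NULL; rownames(training) <- NULL
  structure(list(training = training, probe = probe, nonedges = nonedges,
                 seed = as.integer(rng_seed)),
            class = "link_split")
}

#' @export
print.link_split <- function(x, ...) {
  cat(sprintf("link_split: %d training / %d probe edges, %d non-edges\n",
              nrow(x$training), nrow(x$probe), nrow(x$nonedges)))
  invisible(x)
}

# Sample k distinct non-adjacent node pairs (uses the current RNG stream).
# Rejection sampling first; on a dense graph, falls back to enumerating the
# complement.
sample_nonedges <- function(graph, k) {
  nodes <- graph$nodes
  n <- length(nodes)
  has <- new_edge_env(graph$edges$from, graph$edges$to)
  chosen <- new.env(hash = TRUE, parent = emptyenv())
  out_from <- character(k); out_to <- character(k)
  got <- 0L
  attempts <- 0L
  budget <- max(1000L * k, 10000L)
  while (got < k && attempts < budget) {
    attempts <- attempts + 1L
    ij <- sample.int(n, 2L)
    a <- nodes[ij[1]]; b <- nodes[ij[2]]
    key <- edge_key(a, b)
    if (env_has(has, key) || env_has(chosen, key)) next
    got <- got + 1L
    assign(key, TRUE, envir = chosen)
    if (a < b) { out_from[got] <- a; out_to[got] <- b }
    else       { out_from[got] <- b; out_to[got] <- a }
  }
  if (got < k) {
    # dense graph: enumerate the complement and sample what is still needed
    all_pairs <- utils::combn(nodes, 2)
    keys <- edge_key(all_pairs[1, ], all_pairs[2, ])
    free <- which(!keys %in% c(edge_key(graph$edges$from, graph$edges$to),
                               edge_key(out_from[seq_len(got)],
                                        out_to[seq_len(got)])))
    need <- k - got
    if (length(free) < need) stop_arg("not enough non-edges available")
    take <- free[sample.int(length(free), need)]
    out_from[(got + 1L):k] <- pmin(all_pairs[1, take], all_pairs[2, take])
    out_to[(got + 1L):k] <- pmax(all_pairs[1, take], all_pairs[2, take])
  }
  data.frame(from = out_from, to = out_to, stringsAsFactors = FALSE)
}

#' AUC for link prediction
#'
#' Probability that a probe (hidden true edge) score exceeds a non-edge
#' score, with half credit for ties: over `n` score comparisons of which
#' `n1` have the probe strictly higher and `n2` are equal,
#' `AUC = (n1 + 0.5 n2) / n`.  `"exhaustive"` compares all
#' `|probe| x |nonedge|` ordered pairs; `"sampled"` draws `n_comparisons`
#' random pairs (seeded), the classical estimator for large candidate sets.
#'
#' @param probe_scores,nonedge_scores non-empty numeric vectors.
#' @param mode `"exhaustive"` (default) or `"sampled"`.
#' @param n_comparisons number of sampled comparisons (sampled mode only).
#' @param rng_seed integer seed (sampled mode only).
#' @return A number in \[0, 1\].
#' @examples
#' auc_score(c(3, 1), c(2, 2))   # 0.5
#' @export
auc_score <- function(probe_scores, nonedge_scores,
                      mode = c("exhaustive", "sampled"),
                      n_comparisons = 10000L, rng_seed = NULL) {
  mode <- match.arg(mode)
  if (!length(probe_scores) || !length(nonedge_scores)) {
    stop_arg("score vectors must be non-empty")
  }
  if (mode == "exhaustive") {
    higher <- sum(vapply(probe_scores,
                         function(p) sum(nonedge_scores < p), numeric(1)))
    equal <- sum(vapply(probe_scores,
                        function(p) sum(nonedge_scores == p), numeric(1)))
    n <- length(probe_scores) * length(nonedge_scores)
    (higher + 0.5 * equal) / n
  } else {
    if (is.null(rng_seed)) stop_arg("sampled mode needs rng_seed")
    withr::with_seed(rng_seed, {
      p <- probe_scores[sample.int(length(probe_scores), n_comparisons,
                                   replace = TRUE)]
      q <- nonedge_scores[sample.int(length(nonedge_scores), n_comparisons,
                                     replace = TRUE)]
      (sum(p > q) + 0.5 * sum(p == q)) / n_comparisons
    })
  }
}

#' Precision of the top-L ranked candidates
#'
#' Sorts the candidate pairs (probe plus non-edges) by score in descending
#' order — equal scores permuted uniformly at random under `rng_seed` — and
#' returns `m / L` where `m` is how many of the top `L` are probe edges.
#'
#' @param scores a `score_table` (or data frame with columns `node_x`,
#'   `node_y`, `score`) over the candidate pairs.
#' @param probe the hidden true edges: an edge data frame or even-length
#'   label vector.
#' @param L depth of the ranking to inspect, `1 <= L <=` number of
#'   candidates.  A common choice is `L = |probe|`, where a perfect ranking
#'   scores 1.
#' @param rng_seed integer seed for tie permutation.
#' @return A number in \[0, 1\].
#' @export
precision_at <- function(scores, probe, L, rng_seed) {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    stop_arg("scores must be a non-empty score table")
  }
  if (L < 1 || L > nrow(scores)) stop_arg("L out of range")
  probe_keys <- if (is.data.frame(probe)) {
    edge_key(as.character(probe[[1]]), as.character(probe[[2]]))
  } else {
    subset_keys(probe)
  }
  keys <- edge_key(scores$node_x, scores$node_y)
  shuffle <- withr::with_seed(rng_seed, sample.int(nrow(scores)))
  ord <- order(-scores$score, shuffle)
  top <- keys[ord[seq_len(L)]]
  sum(top %in% probe_keys) / L
}

# --- experiment orchestration -----------------------------------------------

# Normalise a variant given as a string or list(kind = ..., params) into a
# canonical spec with a printable label.
as_variant <- function(variant) {
  if (is.character(variant) && length(variant) == 1) variant <- list(kind = variant)
  if (!is.list(variant) || is.null(variant$kind)) {
    stop_arg("variant must be a kind string or list(kind = ...)")
  }
  kinds <- c("original", "1k", "structure", "weight",
             "rich_club_enhance", "rich_club_destroy",
             "assortative", "disassortative",
             "1k_strong", "1k_weak", "1k_random")
  if (!variant$kind %in% kinds) {
    stop_arg("unknown variant kind: ", variant$kind,
             " (expected one of ", paste(kinds, collapse = ", "), ")")
  }
  variant$label <- variant$label %||% variant$kind
  variant
}

# Apply a null-model variant to a graph under a derived seed.  Returns
# list(graph, report); "original" passes the graph through.
apply_variant <- function(graph, variant, seed) {
  v <- as_variant(variant)
  res <- switch(v$kind,
    original = return(list(graph = graph, report = NULL)),
    "1k" = rewire_1k(graph, n_swaps = v$n_swaps %||% (2L * n_edges(graph)),
                     rng_seed = seed),
    structure = shuffle_structure(graph,
                                  n_swaps = v$n_swaps %||% (2L * n_edges(graph)),
                                  mode = v$mode %||% "exact",
                                  tolerance = v$tolerance %||% 0.05,
                                  rng_seed = seed),
    weight = shuffle_weights(graph,
                             n_swaps = v$n_swaps %||% (2L * n_edges(graph)),
                             rng_seed = seed),
    rich_club_enhance = rewire_rich_club(graph,
                                         rich_fraction = v$rich_fraction %||% 0.05,
                                         direction = "enhance",
                                         max_iters = v$max_iters %||% (2L * n_edges(graph)),
                                         rng_seed = seed),
    rich_club_destroy = rewire_rich_club(graph,
                                         rich_fraction = v$rich_fraction %||% 0.05,
                                         direction = "destroy",
                                         max_iters = v$max_iters %||% (2L * n_edges(graph)),
                                         rng_seed = seed),
    assortative = rewire_assortativity(graph, "assortative",
                                       n_swaps = v$n_swaps %||% (2L * n_edges(graph)),
                                       rng_seed = seed),
    disassortative = rewire_assortativity(graph, "disassortative",
                                          n_swaps = v$n_swaps %||% (2L * n_edges(graph)),
                                          rng_seed = seed),
    "1k_strong" = ,
    "1k_weak" = ,
    "1k_random" = {
      sub <- switch(v$kind,
        "1k_strong" = partition_strong_weak(graph, derive_seed(seed, "part"))$strong,
        "1k_weak" = partition_strong_weak(graph, derive_seed(seed, "part"))$weak,
        "1k_random" = random_half(graph, derive_seed(seed, "part")))
      rewire_1k_subset(graph, sub, n_swaps = v$n_swaps, rng_seed = seed)
    })
  list(graph = res$graph, report = res)
}

#' Run a link-prediction experiment sweep
#'
#' Orchestrates the full evaluation protocol over a factorial grid of
#' network variants, similarity indices, weight exponents and repeats.  For
#' every (variant, repeat): the variant's null model is applied to the full
#' graph under a derived seed (`null_scope = "pre_split"`, the default), the
#' resulting network is split into training / probe / non-edges, all
#' candidate pairs are scored on the training graph for every (index,
#' alpha), and AUC (exhaustive) and precision at `L` are recorded.  With
#' `null_scope = "post_split"` the original graph is split first and the
#' rewiring is applied to the training graph only.
#'
#' All randomness is derived from `rng_seed` by keyed hashing, so adding a
#' variant or index does not perturb the other cells, and the whole sweep is
#' bit-reproducible.
#'
#' @param graph a [wgraph()].
#' @param indices character vector of index names (see [score_pair()]).
#' @param alpha_grid numeric vector of weight exponents.
#' @param repeats number of independent splits per cell.
#' @param variants list of variant kinds (strings) or specs
#'   (`list(kind = , ...)`): `"original"`, `"1k"`, `"structure"`,
#'   `"weight"`, `"rich_club_enhance"`, `"rich_club_destroy"`,
#'   `"assortative"`, `"disassortative"`, `"1k_strong"`, `"1k_weak"`,
#'   `"1k_random"`.
#' @param test_fraction fraction of the probe pool hidden per split.
#' @param probe_pool which edges the probe is drawn from: `"all"`, the
#'   `"strong"` or `"weak"` tie half, or a `"random-half"`.
#' @param null_scope `"pre_split"` or `"post_split"` (see above).
#' @param L precision depth; `NULL` (default) uses `|probe|`.
#' @param rng_seed master integer seed.
#' @return A `sweep_table`: data frame with columns `variant`, `index`,
#'   `alpha`, `repeat_id`, `auc`, `precision`, and attribute `alpha_grid`.
#' @export
run_sweep <- function(graph, indices = "WCN",
                      alpha_grid = default_alpha_grid(),
                      repeats = 10L,
                      variants = list("original"),
                      test_fraction = 0.1,
                      probe_pool = c("all", "strong", "weak", "random-half"),
                      null_scope = c("pre_split", "post_split"),
                      L = NULL, rng_seed) {
  assert_wgraph(graph)
  probe_pool <- match.arg(probe_pool)
  null_scope <- match.arg(null_scope)
  indices <- vapply(indices, match_index, character(1), USE.NAMES = FALSE)
  if (repeats < 1) stop_arg("repeats must be >= 1")
  if (!length(alpha_grid)) stop_arg("alpha_grid must be non-empty")
  rows <- vector("list", 0L)
  for (variant in variants) {
    v <- as_variant(variant)
    for (r in seq_len(repeats)) {
      vseed <- derive_seed(rng_seed, "variant", v$label, r)
      sseed <- derive_seed(rng_seed, "split", v$label, r)
      if (null_scope == "pre_split") {
        gv <- apply_variant(graph, v, vseed)$graph
        split <- split_with_pool(gv, test_fraction, probe_pool, sseed)
        gtrain <- wgraph(split$training, nodes = gv$nodes)
      } else {
        split <- split_with_pool(graph, test_fraction, probe_pool, sseed)
        gtrain0 <- wgraph(split$training, nodes = graph$nodes)
        gtrain <- apply_variant(gtrain0, v, vseed)$graph
      }
      cand <- rbind(split$probe[, c("from", "to")], split$nonedges)
      ctx <- score_context(gtrain)
      profiles <- pair_profiles(ctx, cand)
      n_probe <- nrow(split$probe)
      is_probe <- seq_len(nrow(cand)) <= n_probe
      L_r <- L %||% n_probe
      for (index in indices) {
        weighted <- index %in% c("WCN", "WAA", "WRA")
        cached <- NULL
        for (alpha in alpha_grid) {
          if (weighted || is.null(cached)) {
            s <- vapply(profiles, profile_score, numeric(1),
                        index = index, alpha = alpha)
            cached <- s
          } else {
            s <- cached
          }
          auc <- auc_score(s[is_probe], s[!is_probe])
          tie_seed <- derive_seed(rng_seed, "ties", v$label, r, index,
                                  format(alpha))
          st <- data.frame(node_x = cand$from, node_y = cand$to, score = s,
                           stringsAsFactors = FALSE)
          prec <- precision_at(st, split$probe, L_r, tie_seed)
          rows[[length(rows) + 1L]] <- data.frame(
            variant = v$label, index = index, alpha = alpha, repeat_id = r,
            auc = auc, precision = prec, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha_grid") <- alpha_grid
  class(out) <- c("sweep_table", "data.frame")
  out
}

split_with_pool <- function(g, test_fraction, probe_pool, seed) {
  pool <- switch(probe_pool,
    all = NULL,
    strong = partition_strong_weak(g, derive_seed(seed, "pool"))$strong,
    weak = partition_strong_weak(g, derive_seed(seed, "pool"))$weak,
    "random-half" = random_half(g, derive_seed(seed, "pool")))
  split_edges(g, test_fraction, restrict_to = pool, rng_seed = seed)
}

#' Reduce a sweep to per-cell maxima over the exponent grid
#'
#' Summarises a [run_sweep()] table the way result tables for this protocol
#' are customarily reported: for every (variant, index), the maximum over
#' the alpha grid of either the repeat-mean (`"max_of_means"`, default) or
#' of every individual run (`"max_of_all"`), for both AUC and precision,
#' with the arg-max alpha.
#'
#' @param table a `sweep_table` from [run_sweep()].
#' @param reducer `"max_of_means"` or `"max_of_all"`.
#' @return A data frame with one row per (variant, index):
#'   `auc`, `auc_alpha`, `precision`, `precision_alpha`.
#' @export
max_over_alpha <- function(table, reducer = c("max_of_means", "max_of_all")) {
  reducer <- match.arg(reducer)
  if (!nrow(table)) stop_arg("empty sweep table")
  df <- as.data.frame(table)
  agg_fun <- if (reducer == "max_of_means") mean else max
  agg <- stats::aggregate(cbind(auc, precision) ~ variant + index + alpha,
                          data = df, FUN = agg_fun)
  cells <- unique(agg[, c("variant", "index")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- agg[agg$variant == cells$variant[i] & agg$index == cells$index[i], ]
    ia <- which.max(sub$auc); ip <- which.max(sub$precision)
    data.frame(variant = cells$variant[i], index = cells$index[i],
               auc = sub$auc[ia], auc_alpha = sub$alpha[ia],
               precision = sub$precision[ip], precision_alpha = sub$alpha[ip],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
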