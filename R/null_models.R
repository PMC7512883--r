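# Null-model rewiring algorithms.
#
# All five operations return a fresh graph (inputs are never modified) inside
# a `null_report` carrying swap counters and conservation diagnostics.  Every
# operation preserves the node set, |E|, the degree sequence and the weight
# multiset; the individual operations preserve more (see each contract).
# Rejection sampling is bounded by an attempt budget of 100 * target swaps so
# saturated or degenerate graphs terminate with a partial result and a
# warning rather than hanging.

new_null_report <- function(graph, kind, seed, target, attempted, succeeded,
                            warnings = character(), diagnostics = list()) {
  structure(list(graph = graph, kind = kind, seed = seed, target = target,
                 attempted = attempted, succeeded = succeeded,
                 warnings = warnings, diagnostics = diagnostics),
            class = "null_report")
}

#' @export
print.null_report <- function(x, ...) {
  cat(sprintf("null_report [%s]: %d/%d swaps in %d attempts (seed %d)\n",
              x$kind, x$succeeded, x$target, x$attempted, x$seed))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

budget_factor <- 100L

finish_report <- function(g, from, to, w, kind, seed, target, attempted,
                          succeeded, warnings = character(),
                          diagnostics = list()) {
  out <- wgraph(data.frame(from = from, to = to, weight = w,
                           stringsAsFactors = FALSE),
                nodes = g$nodes)
  if (succeeded < target) {
    msg <- sprintf(
      "%s: attempt budget exhausted after %d successful swaps (target %d)",
      kind, succeeded, target)
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  }
  new_null_report(out, kind, seed, target, attempted, succeeded,
                  warnings, diagnostics)
}

#' Degree-preserving (1k) randomisation
#'
#' Randomises a weighted network by repeated double-edge swaps: two edges
#' (A,B) and (C,D) with four distinct endpoints are replaced by (A,D) and
#' (B,C) when neither replacement already exists.  Each removed edge's weight
#' travels with its first endpoint — (A,D) inherits w(A,B) and (B,C)
#' inherits w(C,D) — so the degree sequence and the weight multiset are both
#' preserved exactly while topology--weight correlations are destroyed.
#' Swaps that would create a self-loop or parallel edge are rejected and
#' retried; `n_swaps` counts successes, not attempts.
#'
#' @param graph a [wgraph()] with at least 2 edges.
#' @param n_swaps requested number of successful swaps; the default `2 * |E|`
#'   is enough to fully randomise the network.
#' @param rng_seed integer seed; identical seed and input give a
#'   bit-identical result.
#' @return A `null_report` whose `graph` element is the rewired network.
#' @export
rewire_1k <- function(graph, n_swaps = 2L * n_edges(graph), rng_seed) {
  assert_wgraph(graph)
  rewire_1k_engine(graph, seq_len(n_edges(graph)), n_swaps, rng_seed,
                   kind = "ONE_K")
}

# Shared engine for rewire_1k and the subset-restricted variant: both swap
# edges drawn from `subset_idx` (row indices into graph$edges).  New edges
# occupy the slots of the edges they replace, so subset membership is
# inherited automatically and the complement is untouched.
rewire_1k_engine <- function(graph, subset_idx, n_swaps, rng_seed, kind) {
  if (n_edges(graph) < 2) {
    return(new_null_report(graph, kind, as.integer(rng_seed), n_swaps, 0L, 0L,
                           warnings = "graph too small to swap"))
  }
  if (n_swaps < 0) stop_arg("n_swaps must be >= 0")
  from <- graph$edges$from; to <- graph$edges$to; w <- graph$edges$weight
  if (n_swaps == 0) {
    return(new_null_report(graph, kind, as.integer(rng_seed), 0L, 0L, 0L))
  }
  has <- new_edge_env(from, to)
  n_sub <- length(subset_idx)
  attempted <- 0L; succeeded <- 0L
  budget <- budget_factor * n_swaps
  withr::with_seed(rng_seed, {
    while (succeeded < n_swaps && attempted < budget) {
      attempted <- attempted + 1L
      ij <- subset_idx[sample.int(n_sub, 2L)]
      a <- from[ij[1]]; b <- to[ij[1]]
      cc <- from[ij[2]]; dd <- to[ij[2]]
      if (stats::runif(1) < 0.5) { tmp <- cc; cc <- dd; dd <- tmp }
      if (anyDuplicated(c(a, b, cc, dd))) next
      k1 <- edge_key(a, dd); k2 <- edge_key(cc, b)
      if (env_has(has, k1) || env_has(has, k2)) next
      rm(list = c(edge_key(a, b), edge_key(cc, dd)), envir = has)
      assign(k1, TRUE, envir = has); assign(k2, TRUE, envir = has)
      if (a < dd) { from[ij[1]] <- a; to[ij[1]] <- dd }
      else        { from[ij[1]] <- dd; to[ij[1]] <- a }
      if (cc < b) { from[ij[2]] <- cc; to[ij[2]] <- b }
      else        { from[ij[2]] <- b; to[ij[2]] <- cc }
      succeeded <- succeeded + 1L
    }
  })
  finish_report(graph, from, to, w, kind, as.integer(rng_seed), n_swaps,
                attempted, succeeded)
}

#' Structure-shuffling null model
#'
#' Randomises topology while preserving each node's strength: endpoint swaps
#' are restricted to pairs of edges with equal weight (`mode = "exact"`), so
#' every node exchanges an incident weight for an identical one.  In
#' `mode = "nearest"` the partner is the edge whose weight is closest to the
#' first edge's among all edges, accepted only when the relative weight
#' difference is at most `tolerance`; the resulting per-node strength drift
#' is accumulated and reported in `diagnostics$strength_drift`.
#'
#' @inheritParams rewire_1k
#' @param mode `"exact"` (equal weights only, strengths preserved exactly)
#'   or `"nearest"` (approximate-weight partners).
#' @param tolerance maximum relative weight difference accepted in
#'   `"nearest"` mode (default 0.05, keeping per-swap strength drift small).
#' @return A `null_report`; `diagnostics$strength_drift` is a named vector of
#'   accumulated absolute weight change per node (all zero in exact mode).
#' @export
shuffle_structure <- function(graph, n_swaps = 2L * n_edges(graph),
                              mode = c("exact", "nearest"), tolerance = 0.05,
                              rng_seed) {
  assert_wgraph(graph)
  mode <- match.arg(mode)
  kind <- "STRUCTURE"
  if (n_edges(graph) < 2) {
    return(new_null_report(graph, kind, as.integer(rng_seed), n_swaps, 0L, 0L,
                           warnings = "graph too small to swap"))
  }
  if (n_swaps < 0) stop_arg("n_swaps must be >= 0")
  from <- graph$edges$from; to <- graph$edges$to; w <- graph$edges$weight
  has <- new_edge_env(from, to)
  m <- length(from)
  drift <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  attempted <- 0L; succeeded <- 0L
  budget <- budget_factor * max(n_swaps, 1L)
  # In exact mode, partners are only ever drawn inside a weight class; if no
  # weight value occurs twice there is nothing to shuffle at all.
  if (mode == "exact" && !anyDuplicated(w)) {
    msg <- "no pair of equal-weight edges exists; graph returned unchanged"
    warning(msg, call. = FALSE)
    return(new_null_report(graph, kind, as.integer(rng_seed), n_swaps,
                           0L, 0L, warnings = msg,
                           diagnostics = list(strength_drift = drift)))
  }
  withr::with_seed(rng_seed, {
    while (succeeded < n_swaps && attempted < budget) {
      attempted <- attempted + 1L
      i <- sample.int(m, 1L)
      if (mode == "exact") {
        partners <- which(w == w[i]); partners <- partners[partners != i]
        if (!length(partners)) next
        j <- partners[sample.int(length(partners), 1L)]
      } else {
        d <- abs(w - w[i]); d[i] <- Inf
        j <- which.min(d)
        if (abs(w[i] - w[j]) / max(w[i], w[j]) > tolerance) next
        # several edges may be equally close; pick among them at random
        near <- which(d == d[j])
        j <- near[sample.int(length(near), 1L)]
      }
      a <- from[i]; b <- to[i]
      cc <- from[j]; dd <- to[j]
      if (stats::runif(1) < 0.5) { tmp <- cc; cc <- dd; dd <- tmp }
      if (anyDuplicated(c(a, b, cc, dd))) next
      k1 <- edge_key(a, dd); k2 <- edge_key(cc, b)
      if (env_has(has, k1) || env_has(has, k2)) next
      rm(list = c(edge_key(a, b), edge_key(cc, dd)), envir = has)
      assign(k1, TRUE, envir = has); assign(k2, TRUE, envir = has)
      if (a < dd) { from[i] <- a; to[i] <- dd } else { from[i] <- dd; to[i] <- a }
      if (cc < b) { from[j] <- cc; to[j] <- b } else { from[j] <- b; to[j] <- cc }
      if (w[i] != w[j]) {
        dw <- abs(w[i] - w[j])
        drift[b] <- drift[b] + dw   # b exchanged w[i] for w[j]
        drift[dd] <- drift[dd] + dw # d exchanged w[j] for w[i]
      }
      succeeded <- succeeded + 1L
    }
  })
  finish_report(graph, from, to, w, kind, as.integer(rng_seed), n_swaps,
                attempted, succeeded,
                diagnostics = list(strength_drift = drift))
}

#' Weight-shuffling null model
#'
#' Randomises weight placement on a fixed topology: each step draws two edges
#' with different weights and exchanges the weights.  The edge set is
#' untouched, so all structural statistics are preserved while the
#' correlation between weights and their position in the network is
#' destroyed.
#'
#' @inheritParams rewire_1k
#' @return A `null_report`.  If all weights are equal no shuffle is possible:
#'   the input is returned with `succeeded = 0` and a warning.
#' @export
shuffle_weights <- function(graph, n_swaps = 2L * n_edges(graph), rng_seed) {
  assert_wgraph(graph)
  kind <- "WEIGHT"
  if (n_edges(graph) < 2) {
    return(new_null_report(graph, kind, as.integer(rng_seed), n_swaps, 0L, 0L,
                           warnings = "graph too small to swap"))
  }
  w <- graph$edges$weight
  if (length(unique(w)) == 1L) {
    msg <- "all edge weights are equal; nothing to shuffle"
    warning(msg, call. = FALSE)
    return(new_null_report(graph, kind, as.integer(rng_seed), n_swaps, 0L, 0L,
                           warnings = msg))
  }
  m <- length(w)
  attempted <- 0L; succeeded <- 0L
  budget <- budget_factor * max(n_swaps, 1L)
  withr::with_seed(rng_seed, {
    while (succeeded < n_swaps && attempted < budget) {
      attempted <- attempted + 1L
      ij <- sample.int(m, 2L)
      if (w[ij[1]] == w[ij[2]]) next
      tmp <- w[ij[1]]; w[ij[1]] <- w[ij[2]]; w[ij[2]] <- tmp
      succeeded <- succeeded + 1L
    }
  })
  finish_report(graph, graph$edges$from, graph$edges$to, w, kind,
                as.integer(rng_seed), n_swaps, attempted, succeeded)
}

# Rich set: top ceil(fraction * |V|) nodes by strength, ties broken by label
# so the designation is deterministic.
rich_set <- function(graph, rich_fraction) {
  if (!(rich_fraction > 0 && rich_fraction < 1)) {
    stop_arg("rich_fraction must be in (0, 1)")
  }
  s <- strength_vector(graph)
  k <- ceiling(rich_fraction * length(graph$nodes))
  names(s)[order(-s, names(s), method = "radix")][seq_len(k)]
}

#' Density of connections inside the rich club
#'
#' The rich set is the top `ceil(rich_fraction * |V|)` nodes by strength
#' (ties broken by label).  The coefficient is the number of edges with both
#' endpoints in the rich set divided by the number of possible rich pairs.
#'
#' @param graph a [wgraph()].
#' @param rich_fraction fraction of nodes designated rich, in (0, 1).
#' @return A number in \[0, 1\].
#' @export
rich_club_coefficient <- function(graph, rich_fraction) {
  assert_wgraph(graph)
  rich <- rich_set(graph, rich_fraction)
  rich_coeff_on(graph$edges, rich)
}

rich_coeff_on <- function(edges, rich) {
  if (length(rich) < 2) stop_arg("rich set must contain at least 2 nodes")
  inside <- sum(edges$from %in% rich & edges$to %in% rich)
  inside / choose(length(rich), 2)
}

#' Rich-club enhancing / destroying rewiring
#'
#' Tendentious degree-preserving rewiring that raises or lowers the density
#' of connections among the strongest nodes.  The rich set (top
#' `ceil(rich_fraction * |V|)` by strength) is frozen at the start of the
#' run, since moves shift strengths.
#'
#' `direction = "enhance"`: pick an unconnected rich pair (A, B), a non-rich
#' neighbour C of A and a non-rich neighbour D of B with C != D and (C, D)
#' absent; replace (A,C), (B,D) by (A,B), (C,D).  Each step adds exactly one
#' rich--rich edge, so the coefficient is non-decreasing.
#' `direction = "destroy"` is the inverse move: a connected rich pair is
#' detached onto two non-rich nodes, and the coefficient is non-increasing.
#' Weights travel with the edge contributing the rich endpoint: (A,B)
#' inherits w(A,C) and (C,D) inherits w(B,D) (and conversely when
#' destroying), preserving the weight multiset.
#'
#' The run stops at `max_iters` successful moves, at saturation (coefficient
#' 1 when enhancing, 0 when destroying), or when the attempt budget is
#' exhausted.
#'
#' @inheritParams rewire_1k
#' @param rich_fraction fraction of nodes designated rich, in (0, 1); the
#'   default 0.05 designates the few strongest hubs.
#' @param direction `"enhance"` or `"destroy"`.
#' @param max_iters maximum number of successful moves (default `2 * |E|`).
#' @return A `null_report`; `diagnostics` holds the frozen rich set and the
#'   rich-club coefficient before and after (on that set).
#' @export
rewire_rich_club <- function(graph, rich_fraction = 0.05,
                             direction = c("enhance", "destroy"),
                             max_iters = 2L * n_edges(graph), rng_seed) {
  assert_wgraph(graph)
  direction <- match.arg(direction)
  kind <- if (direction == "enhance") "RICH_CLUB_ENHANCE" else "RICH_CLUB_DESTROY"
  rich <- rich_set(graph, rich_fraction)
  if (length(rich) < 2) stop_arg("rich set must contain at least 2 nodes")
  from <- graph$edges$from; to <- graph$edges$to; w <- graph$edges$weight
  # slot index keyed by unordered pair; doubles as the edge-existence test
  slot <- new_edge_env(from, to)
  is_rich <- stats::setNames(graph$nodes %in% rich, graph$nodes)
  n_rich <- length(rich)
  max_pairs <- choose(n_rich, 2)
  inside <- sum(is_rich[from] & is_rich[to])
  coeff_before <- inside / max_pairs
  attempted <- 0L; succeeded <- 0L; last_success <- 0L
  budget <- budget_factor * max(max_iters, 1L)
  # a long run of consecutive rejections is read as saturation: no valid
  # move is being found even though the coefficient is not at its extreme
  stall_limit <- max(2000L, 10L * as.integer(max_pairs))
  withr::with_seed(rng_seed, {
    while (succeeded < max_iters && attempted < budget) {
      if (direction == "enhance" && inside == max_pairs) break
      if (direction == "destroy" && inside == 0) break
      if (attempted - last_success >= stall_limit) break
      attempted <- attempted + 1L
      ab <- rich[sample.int(n_rich, 2L)]
      A <- ab[1]; B <- ab[2]
      kab <- edge_key(A, B)
      if (direction == "enhance") {
        if (env_has(slot, kab)) next
        # non-rich neighbours of A and of B in the current graph
        iA <- which((from == A & !is_rich[to]) | (to == A & !is_rich[from]))
        iB <- which((from == B & !is_rich[to]) | (to == B & !is_rich[from]))
        if (!length(iA) || !length(iB)) next
        eA <- iA[sample.int(length(iA), 1L)]
        eB <- iB[sample.int(length(iB), 1L)]
        C <- if (from[eA] == A) to[eA] else from[eA]
        D <- if (from[eB] == B) to[eB] else from[eB]
        if (C == D) next
        kcd <- edge_key(C, D)
        if (env_has(slot, kcd)) next
        # replace (A,C), (B,D) with (A,B), (C,D)
        rm(list = c(edge_key(A, C), edge_key(B, D)), envir = slot)
        set_slot(eA, A, B, environment())   # inherits w[eA] = w(A,C)
        set_slot(eB, C, D, environment())   # inherits w[eB] = w(B,D)
        assign(kab, eA, envir = slot)
        assign(kcd, eB, envir = slot)
        inside <- inside + 1L
      } else {
        if (!env_has(slot, kab)) next
        eAB <- get(kab, envir = slot)
        # an edge joining two non-rich nodes, to be opened up
        icd <- which(!is_rich[from] & !is_rich[to])
        if (!length(icd)) next
        eCD <- icd[sample.int(length(icd), 1L)]
        C <- from[eCD]; D <- to[eCD]
        if (stats::runif(1) < 0.5) { tmp <- C; C <- D; D <- tmp }
        kac <- edge_key(A, C); kbd <- edge_key(B, D)
        if (env_has(slot, kac) || env_has(slot, kbd)) next
        rm(list = c(kab, edge_key(C, D)), envir = slot)
        set_slot(eAB, A, C, environment())  # inherits w(A,B)
        set_slot(eCD, B, D, environment())  # inherits w(C,D)
        assign(kac, eAB, envir = slot)
        assign(kbd, eCD, envir = slot)
        inside <- inside - 1L
      }
      succeeded <- succeeded + 1L
      last_success <- attempted
    }
  })
  # early stop through an extreme coefficient or a stalled search means no
  # further valid move exists (saturation); running out of attempt budget
  # with intermittent progress is reported as exhaustion instead
  saturated <- succeeded < max_iters && attempted < budget
  rep <- finish_report(graph, from, to, w, kind, as.integer(rng_seed),
                       if (saturated) succeeded else max_iters,
                       attempted, succeeded,
                       diagnostics = list(
                         rich_nodes = rich,
                         coefficient_before = coeff_before,
                         coefficient_after = inside / max_pairs,
                         saturated = saturated))
  rep
}

# Rewrite edge slot `i` to join u--v (canonical orientation), in the caller's
# from/to vectors.  Weight stays with the slot.
set_slot <- function(i, u, v, env) {
  if (u < v) { env$from[i] <- u; env$to[i] <- v }
  else       { env$from[i] <- v; env$to[i] <- u }
  invisible(NULL)
}

#' Pearson correlation of endpoint strengths
#'
#' Strength analogue of degree assortativity: the Pearson correlation of
#' (s(x), s(y)) over all edges, with both orientations of every edge
#' included so the statistic is symmetric.
#'
#' @param graph a [wgraph()] with at least 2 edges.
#' @return A number in \[-1, 1\].  Errors when the endpoint strengths have
#'   zero variance (e.g. a regular graph with equal weights), where the
#'   correlation is undefined.
#' @export
strength_assortativity <- function(graph) {
  assert_wgraph(graph)
  if (n_edges(graph) < 2) stop_arg("need at least 2 edges")
  s <- strength_vector(graph)
  x <- c(s[graph$edges$from], s[graph$edges$to])
  y <- c(s[graph$edges$to], s[graph$edges$from])
  if (stats::sd(x) == 0) {
    stop_arg("endpoint strengths have zero variance; assortativity undefined")
  }
  unname(stats::cor(x, y))
}

#' Assortativity-steering rewiring
#'
#' Degree-preserving rewiring that pushes the strength mixing pattern of the
#' network toward assortative (strong connects to strong) or disassortative
#' (strong connects to weak) pairing.  Each step draws two edges with four
#' distinct endpoints, ranks the endpoints by current strength (ties broken
#' by label), and re-pairs them:
#'
#' * `"assortative"`: (1st, 2nd) and (3rd, 4th);
#' * `"disassortative"`: (1st, 4th) and (2nd, 3rd).
#'
#' The step is applied only when both target edges are absent (which also
#' rejects steps whose target pairing equals the current one).  The new edge
#' containing the first-ranked endpoint inherits the weight of the removed
#' edge that contributed that endpoint; the other new edge takes the
#' remaining weight, so the weight multiset is conserved exactly.  Because
#' carried weights shift strengths, the assortativity moves toward the
#' target over the run rather than monotonically per step.
#'
#' @inheritParams rewire_1k
#' @param direction `"assortative"` or `"disassortative"`.
#' @return A `null_report`; `diagnostics` records the strength
#'   assortativity before and after (when defined).
#' @export
rewire_assortativity <- function(graph,
                                 direction = c("assortative", "disassortative"),
                                 n_swaps = 2L * n_edges(graph), rng_seed) {
  assert_wgraph(graph)
  direction <- match.arg(direction)
  kind <- if (direction == "assortative") "ASSORTATIVE" else "DISASSORTATIVE"
  if (n_edges(graph) < 2) {
    return(new_null_report(graph, kind, as.integer(rng_seed), n_swaps, 0L, 0L,
                           warnings = "graph too small to swap"))
  }
  from <- graph$edges$from; to <- graph$edges$to; w <- graph$edges$weight
  has <- new_edge_env(from, to)
  s <- strength_vector(graph)
  m <- length(from)
  assort_before <- tryCatch(strength_assortativity(graph),
                            error = function(e) NA_real_)
  attempted <- 0L; succeeded <- 0L
  budget <- budget_factor * max(n_swaps, 1L)
  withr::with_seed(rng_seed, {
    while (succeeded < n_swaps && attempted < budget) {
      attempted <- attempted + 1L
      ij <- sample.int(m, 2L)
      e1 <- ij[1]; e2 <- ij[2]
      ends <- c(from[e1], to[e1], from[e2], to[e2])
      if (anyDuplicated(ends)) next
      ranked <- ends[order(-s[ends], ends, method = "radix")]
      if (direction == "assortative") {
        t1 <- ranked[1:2]; t2 <- ranked[3:4]
      } else {
        t1 <- ranked[c(1, 4)]; t2 <- ranked[2:3]
      }
      k1 <- edge_key(t1[1], t1[2]); k2 <- edge_key(t2[1], t2[2])
      if (env_has(has, k1) || env_has(has, k2)) next
      # weight routing: the edge holding the top-ranked endpoint takes the
      # weight of the removed edge that contributed that endpoint
      w1 <- w[e1]; w2 <- w[e2]
      top_from_e1 <- ranked[1] %in% c(from[e1], to[e1])
      wt1 <- if (top_from_e1) w1 else w2
      wt2 <- if (top_from_e1) w2 else w1
      rm(list = c(edge_key(from[e1], to[e1]), edge_key(from[e2], to[e2])),
         envir = has)
      assign(k1, TRUE, envir = has); assign(k2, TRUE, envir = has)
      # update strengths: remove old incident weights, add new
      s[from[e1]] <- s[from[e1]] - w1; s[to[e1]] <- s[to[e1]] - w1
      s[from[e2]] <- s[from[e2]] - w2; s[to[e2]] <- s[to[e2]] - w2
      set_slot(e1, t1[1], t1[2], environment()); w[e1] <- wt1
      set_slot(e2, t2[1], t2[2], environment()); w[e2] <- wt2
      s[t1] <- s[t1] + wt1
      s[t2] <- s[t2] + wt2
      succeeded <- succeeded + 1L
    }
  })
  rep <- finish_report(graph, from, to, w, kind, as.integer(rng_seed),
                       n_swaps, attempted, succeeded)
  rep$diagnostics$assortativity_before <- assort_before
  rep$diagnostics$assortativity_after <-
    tryCatch(strength_assortativity(rep$graph), error = function(e) NA_real_)
  rep
}
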