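# Conservation laws and single-operation semantics of the five null models.

null_ops <- list(
  one_k = function(g, seed) rewire_1k(g, rng_seed = seed),
  structure = function(g, seed) shuffle_structure(g, rng_seed = seed),
  weight = function(g, seed) shuffle_weights(g, rng_seed = seed),
  assortative = function(g, seed) rewire_assortativity(g, "assortative",
                                                       rng_seed = seed),
  rich_enhance = function(g, seed) rewire_rich_club(g, 0.05, "enhance",
                                                    rng_seed = seed)
)

test_that("every null model conserves nodes, edge count, degrees, weights", {
  for (seed in 1:4) {
    g <- generate_network(120, 2, rng_seed = seed, coupling = 0.5)
    for (op in names(null_ops)) {
      rep <- suppressWarnings(null_ops[[op]](g, seed + 100))
      out <- rep$graph
      expect_no_error(wnetnull:::validate_wgraph(out))
      expect_identical(out$nodes, g$nodes)
      expect_identical(nrow(out$edges), nrow(g$edges))
      expect_identical(degree_multiset(out), degree_multiset(g))
      expect_identical(weight_multiset(out), weight_multiset(g))
      expect_lte(rep$succeeded, rep$attempted)
    }
  }
})

test_that("rewiring is deterministic under a fixed seed and never mutates input", {
  g <- generate_network(80, 2, rng_seed = 3, coupling = 0.3)
  snapshot <- g
  a <- suppressWarnings(rewire_1k(g, rng_seed = 7))
  b <- suppressWarnings(rewire_1k(g, rng_seed = 7))
  expect_true(graph_equal(a$graph, b$graph))
  expect_identical(a$attempted, b$attempted)
  expect_true(graph_equal(g, snapshot))
  c <- suppressWarnings(rewire_1k(g, rng_seed = 8))
  expect_false(graph_equal(a$graph, c$graph))
})

test_that("1k with zero swaps is the identity", {
  g <- toy_g0()
  rep <- rewire_1k(g, n_swaps = 0, rng_seed = 1)
  expect_true(graph_equal(rep$graph, g))
  expect_identical(rep$succeeded, 0L)
})

test_that("1k on a 4-cycle keeps the graph simple and 2-regular", {
  cyc <- wgraph(data.frame(from = c("A", "B", "C", "A"),
                           to = c("B", "C", "D", "D"),
                           weight = c(1, 2, 3, 4)))
  for (seed in 1:10) {
    out <- suppressWarnings(rewire_1k(cyc, n_swaps = 10, rng_seed = seed))$graph
    expect_no_error(wnetnull:::validate_wgraph(out))
    expect_identical(unname(wnetnull:::degree_vector(out)),
                     rep(2L, 4))
    expect_identical(weight_multiset(out), weight_multiset(cyc))
  }
})

test_that("structure shuffling in exact mode preserves every node strength", {
  for (seed in 1:4) {
    g <- generate_network(120, 2, rng_seed = seed)   # integer weights
    rep <- suppressWarnings(shuffle_structure(g, rng_seed = seed + 50))
    expect_identical(strengths_of(rep$graph), strengths_of(g))
    expect_gt(rep$succeeded, 0)
  }
})

test_that("structure shuffling with all-distinct weights is a no-op", {
  g <- gnm_graph(20, 30, 2, weights = seq(0.5, by = 0.31, length.out = 30))
  expect_warning(rep <- shuffle_structure(g, rng_seed = 1), "equal-weight")
  expect_identical(rep$succeeded, 0L)
  expect_true(graph_equal(rep$graph, g))
})

test_that("structure shuffling on uniform weights randomises like 1k", {
  g <- generate_network(100, 2, rng_seed = 5, integer_weights = FALSE)
  g_unif <- wgraph(data.frame(from = g$edges$from, to = g$edges$to,
                              weight = rep(2, nrow(g$edges))))
  r_ss <- suppressWarnings(shuffle_structure(g_unif, rng_seed = 11))
  r_1k <- suppressWarnings(rewire_1k(g_unif, rng_seed = 11))
  expect_identical(r_ss$succeeded, r_ss$target)
  # both scramble a comparable share of the original edge placement
  frac_kept <- function(out) mean(edge_keys_of(out) %in% edge_keys_of(g_unif))
  expect_lt(abs(frac_kept(r_ss$graph) - frac_kept(r_1k$graph)), 0.15)
  expect_lt(frac_kept(r_ss$graph), 0.5)
})

test_that("nearest-weight mode bounds and reports per-node strength drift", {
  g <- gnm_graph(40, 90, 7, weights = round(runif(90, 1, 1.2), 4))
  rep <- suppressWarnings(shuffle_structure(g, n_swaps = 60, mode = "nearest",
                                            tolerance = 0.2, rng_seed = 3))
  expect_gt(rep$succeeded, 0)
  drift <- rep$diagnostics$strength_drift
  s0 <- strengths_of(g); s1 <- strengths_of(rep$graph)
  expect_true(all(abs(s1 - s0[names(s1)]) <= drift[names(s1)] + 1e-9))
  expect_identical(weight_multiset(rep$graph), weight_multiset(g))
})

test_that("weight shuffling permutes weights on a fixed topology", {
  for (seed in 1:4) {
    g <- generate_network(120, 2, rng_seed = seed)
    rep <- suppressWarnings(shuffle_weights(g, rng_seed = seed + 9))
    expect_identical(edge_keys_of(rep$graph), edge_keys_of(g))
    expect_identical(weight_multiset(rep$graph), weight_multiset(g))
  }
  g_eq <- gnm_graph(10, 15, 3, weights = rep(4, 15))
  expect_warning(rep <- shuffle_weights(g_eq, rng_seed = 1), "equal")
  expect_identical(rep$succeeded, 0L)
  expect_true(graph_equal(rep$graph, g_eq))
})

test_that("heavy weight shuffling approaches a uniform weight permutation", {
  # position of the maximum weight should become uniform over the six edges
  g <- gnm_graph(6, 6, 1, weights = c(9, 5, 4, 3, 2, 1))
  counts <- integer(6)
  for (seed in 1:600) {
    out <- shuffle_weights(g, n_swaps = 50 * 6, rng_seed = seed)$graph
    counts[which.max(out$edges$weight)] <- counts[which.max(out$edges$weight)] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("rich-club coefficient counts realised rich-rich links", {
  full <- wgraph(data.frame(t(utils::combn(LETTERS[1:6], 2)), weight = 1))
  expect_identical(rich_club_coefficient(full, 0.5), 1)
  # strongest two nodes (A and B, strength 18) unconnected: coefficient 0
  g <- wgraph(data.frame(from = c("A", "A", "B", "B"),
                         to = c("C", "D", "E", "F"),
                         weight = 9))
  expect_identical(rich_club_coefficient(g, 1 / 3), 0)   # rich = {A, B}
  expect_error(rich_club_coefficient(g, 0.1), "at least 2")
})

test_that("rich-club rewiring is monotone on the frozen rich set", {
  g <- generate_network(100, 3, rng_seed = 21, coupling = 0.5)
  # same seed => same trajectory prefix, so coefficient_after is monotone
  # non-decreasing in max_iters for enhance, non-increasing for destroy
  co_en <- vapply(c(1, 5, 20, 60), function(k) {
    suppressWarnings(rewire_rich_club(g, 0.1, "enhance", k, rng_seed = 2)
    )$diagnostics$coefficient_after
  }, numeric(1))
  expect_true(all(diff(co_en) >= 0))
  rep_en <- suppressWarnings(rewire_rich_club(g, 0.1, "enhance", rng_seed = 2))
  expect_gte(rep_en$diagnostics$coefficient_after,
             rep_en$diagnostics$coefficient_before)
  co_de <- vapply(c(1, 5, 20, 60), function(k) {
    suppressWarnings(rewire_rich_club(g, 0.1, "destroy", k, rng_seed = 2)
    )$diagnostics$coefficient_after
  }, numeric(1))
  expect_true(all(diff(co_de) <= 0))
  rep_de <- suppressWarnings(rewire_rich_club(g, 0.1, "destroy", rng_seed = 2))
  expect_lte(rep_de$diagnostics$coefficient_after,
             rep_de$diagnostics$coefficient_before)
})

test_that("enhance on a complete graph finds no move", {
  full <- wgraph(data.frame(t(utils::combn(LETTERS[1:6], 2)), weight = 1:15))
  rep <- rewire_rich_club(full, 0.5, "enhance", rng_seed = 1)
  expect_identical(rep$succeeded, 0L)
  expect_true(graph_equal(rep$graph, full))
})

test_that("strength assortativity matches hand computations", {
  two <- wgraph(data.frame(from = c("a", "c"), to = c("b", "d"),
                           weight = c(5, 1)))
  expect_equal(strength_assortativity(two), 1)
  path <- wgraph(data.frame(from = c("a", "b"), to = c("b", "c"),
                            weight = c(1, 1)))
  expect_equal(strength_assortativity(path), -1)
  ring <- wgraph(data.frame(from = c("a", "b", "c", "a"),
                            to = c("b", "c", "d", "d"), weight = rep(1, 4)))
  expect_error(strength_assortativity(ring), "zero variance")
})

test_that("assortativity rewiring moves mixing in the commanded direction", {
  g <- generate_network(120, 2, rng_seed = 17, coupling = 0.5)
  rep_a <- suppressWarnings(rewire_assortativity(g, "assortative", rng_seed = 4))
  rep_d <- suppressWarnings(rewire_assortativity(g, "disassortative", rng_seed = 4))
  expect_gt(rep_a$diagnostics$assortativity_after,
            rep_a$diagnostics$assortativity_before)
  expect_lt(rep_d$diagnostics$assortativity_after,
            rep_d$diagnostics$assortativity_before)
})

test_that("a star has no four-distinct-endpoint swap", {
  star <- wgraph(data.frame(from = "hub", to = c("a", "b", "c", "d"),
                            weight = 1:4))
  rep <- suppressWarnings(rewire_assortativity(star, "assortative",
                                               n_swaps = 4, rng_seed = 1))
  expect_identical(rep$succeeded, 0L)
  expect_true(graph_equal(rep$graph, star))
})
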