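test_that("AUC follows the half-credit comparison rule", {
  expect_identical(auc_score(2, 1), 1)
  expect_identical(auc_score(c(1, 1), c(1, 1)), 0.5)
  expect_identical(auc_score(c(3, 1), c(2, 2)), 0.5)
  expect_identical(auc_score(1, 2), 0)
  expect_error(auc_score(numeric(), 1), "non-empty")
})

test_that("exhaustive AUC equals the rank-sum oracle", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
      # integer scores force plenty of ties
      p <- sample(0:5, n1, replace = TRUE) + (seed %% 2) * runif(n1)
      q <- sample(0:5, n2, replace = TRUE) + (seed %% 2) * runif(n2)
    })
    expect_equal(auc_score(p, q), auc_rank_oracle(p, q), tolerance = 1e-12)
  }
})

test_that("sampled AUC converges to the exhaustive value", {
  withr::with_seed(1, {
    p <- rnorm(50, mean = 1)
    q <- rnorm(60)
  })
  exact <- auc_score(p, q)
  for (n in c(2000, 20000)) {
    est <- auc_score(p, q, mode = "sampled", n_comparisons = n, rng_seed = 4)
    expect_lt(abs(est - exact), 3 * sqrt(0.25 / n))
  }
})

test_that("AUC and precision are invariant under monotone score transforms", {
  withr::with_seed(2, {
    p <- sample(1:6, 20, replace = TRUE)
    q <- sample(1:6, 25, replace = TRUE)
  })
  expect_identical(auc_score(p, q), auc_score(exp(p), exp(q)))
  expect_identical(auc_score(p, q), auc_score(2 * p + 1, 2 * q + 1))

  st <- data.frame(node_x = sprintf("p%02d", 1:45),
                   node_y = sprintf("q%02d", 1:45),
                   score = c(p, q))
  probe <- as.character(t(st[1:20, 1:2]))
  p1 <- precision_at(st, probe, L = 20, rng_seed = 9)
  st2 <- st; st2$score <- exp(st2$score)
  expect_identical(precision_at(st2, probe, L = 20, rng_seed = 9), p1)
})

test_that("uninformative scores give AUC near one half", {
  aucs <- vapply(1:50, function(seed) {
    withr::with_seed(seed, auc_score(runif(30), runif(30)))
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.01)
})

test_that("precision rewards correct top-L ranking", {
  st <- data.frame(node_x = c("a", "b", "c", "d"),
                   node_y = c("x", "y", "z", "w"),
                   score = c(9, 8, 2, 1))
  probe <- c("a", "x", "b", "y")
  expect_identical(precision_at(st, probe, L = 2, rng_seed = 1), 1)
  # inverted ranking
  st2 <- data.frame(node_x = c("p", "q"), node_y = c("u", "v"),
                    score = c(1, 2))
  expect_identical(precision_at(st2, c("p", "u"), L = 1, rng_seed = 1), 0)
  expect_error(precision_at(st2, c("p", "u"), L = 3, rng_seed = 1),
               "out of range")
})

test_that("tied scores are broken fairly by the seeded permutation", {
  k <- 5
  st <- data.frame(node_x = sprintf("n%02d", 1:(2 * k)),
                   node_y = sprintf("m%02d", 1:(2 * k)),
                   score = rep(1, 2 * k))
  probe <- as.character(t(st[1:k, 1:2]))
  vals <- vapply(1:300, function(seed) {
    precision_at(st, probe, L = k, rng_seed = seed)
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.5), 3 * se)
})

test_that("edge splitting follows the 10/90 protocol with matched non-edges", {
  g <- gnm_graph(30, 100, 1)
  sp <- split_edges(g, 0.1, rng_seed = 5)
  expect_identical(nrow(sp$probe), 10L)
  expect_identical(nrow(sp$training), 90L)
  expect_identical(nrow(sp$nonedges), 10L)
  # partition and non-edge invariants
  pk <- wnetnull:::edge_key(sp$probe$from, sp$probe$to)
  tk <- wnetnull:::edge_key(sp$training$from, sp$training$to)
  nk <- wnetnull:::edge_key(sp$nonedges$from, sp$nonedges$to)
  expect_length(intersect(pk, tk), 0)
  expect_setequal(c(pk, tk), edge_keys_of(g))
  expect_length(intersect(nk, edge_keys_of(g)), 0)
  expect_false(anyDuplicated(nk) > 0)
  # determinism
  sp2 <- split_edges(g, 0.1, rng_seed = 5)
  expect_identical(sp, sp2)
})

test_that("splitting a near-complete graph fails cleanly", {
  full <- wgraph(data.frame(t(utils::combn(letters[1:6], 2)), weight = 1))
  expect_error(split_edges(full, 0.5, rng_seed = 1), "dense")
})

test_that("probe can be restricted to a designated edge subset", {
  g <- gnm_graph(30, 100, 2)
  p <- partition_strong_weak(g, rng_seed = 1)
  sp <- split_edges(g, 0.2, restrict_to = p$strong, rng_seed = 3)
  expect_identical(nrow(sp$probe), 10L)   # 20% of the 50 strong ties
  pk <- wnetnull:::edge_key(sp$probe$from, sp$probe$to)
  expect_true(all(pk %in% wnetnull:::edge_key(p$strong$from, p$strong$to)))
  # training still holds every unhidden edge, weak ties included
  expect_identical(nrow(sp$training), 90L)
})

test_that("a one-cell sweep equals direct scoring on the same split", {
  g <- generate_network(60, 2, rng_seed = 31)
  seed <- 77
  sw <- run_sweep(g, indices = "CN", alpha_grid = 0, repeats = 1,
                  variants = list("original"), rng_seed = seed)
  expect_identical(nrow(sw), 1L)
  sp <- split_edges(g, 0.1,
                    rng_seed = wnetnull:::derive_seed(seed, "split",
                                                      "original", 1))
  gtrain <- wgraph(sp$training, nodes = g$nodes)
  cand <- rbind(sp$probe[, c("from", "to")], sp$nonedges)
  st <- score_candidates(gtrain, cand, "CN")
  key_st <- wnetnull:::edge_key(st$node_x, st$node_y)
  pk <- wnetnull:::edge_key(sp$probe$from, sp$probe$to)
  is_probe <- key_st %in% pk
  expect_equal(sw$auc, auc_score(st$score[is_probe], st$score[!is_probe]))
  expect_true(sw$precision >= 0 && sw$precision <= 1)
})

test_that("sweeps cover the requested factorial grid deterministically", {
  g <- generate_network(60, 2, rng_seed = 32, coupling = 0.5)
  sw <- suppressWarnings(
    run_sweep(g, indices = c("CN", "WCN"), alpha_grid = c(-0.5, 0.5),
              repeats = 3, variants = list("original", "weight"),
              rng_seed = 5))
  expect_identical(nrow(sw), 2L * 2L * 3L * 2L)
  combos <- unique(sw[, c("variant", "index", "alpha")])
  expect_identical(nrow(combos), 8L)
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
  expect_true(all(sw$precision >= 0 & sw$precision <= 1))
  sw2 <- suppressWarnings(
    run_sweep(g, indices = c("CN", "WCN"), alpha_grid = c(-0.5, 0.5),
              repeats = 3, variants = list("original", "weight"),
              rng_seed = 5))
  expect_identical(sw, sw2)
})

test_that("max_over_alpha reduces to the best exponent per cell", {
  tab <- data.frame(
    variant = "original", index = "WCN",
    alpha = rep(c(-0.5, 0.5), each = 2),
    repeat_id = rep(1:2, 2),
    auc = c(0.9, 0.9, 0.7, 0.7),
    precision = c(0.4, 0.4, 0.8, 0.8))
  out <- max_over_alpha(tab)
  expect_equal(out$auc, 0.9)
  expect_equal(out$auc_alpha, -0.5)
  expect_equal(out$precision, 0.8)
  expect_equal(out$precision_alpha, 0.5)
  # single-alpha table reduces to the means
  tab1 <- tab[tab$alpha == -0.5, ]
  out1 <- max_over_alpha(tab1)
  expect_equal(out1$auc, 0.9)
  expect_equal(out1$precision, 0.4)
  # max_of_all picks the best single run
  tab$auc[1] <- 0.95
  expect_equal(max_over_alpha(tab, "max_of_all")$auc, 0.95)
})
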