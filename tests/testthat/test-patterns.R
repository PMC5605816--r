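test_that("memory patterns and sets enforce the ±1 and uniqueness invariants", {
  expect_error(memory_pattern(c(1, 0, -1)), "\\+1 or -1")
  expect_error(memory_pattern(integer(0)), "non-empty")
  p <- memory_pattern(c(1, -1, 1, -1), label = "x")
  expect_identical(as.integer(p), c(1L, -1L, 1L, -1L))

  expect_error(memory_set(list(memory_pattern(c(1, 1)),
                               memory_pattern(c(1, -1, 1)))),
               "same length")
  M <- cbind(a = c(1L, -1L), b = c(1L, -1L))
  colnames(M) <- c("a", "a")
  expect_error(memory_set(M), "unique")
})

test_that("synthetic generation respects the pairwise overlap bound on every pair", {
  s <- generate_synthetic_patterns(20, 1000, max_abs_overlap = 0.2, seed = 1)
  expect_equal(dim(unclass(s)), c(1000L, 20L))
  expect_true(all(unclass(s) %in% c(-1L, 1L)))
  # check all 190 pairs by direct dot product
  M <- unclass(s)
  for (mu in 1:19) {
    for (nu in (mu + 1):20) {
      expect_lte(abs(sum(M[, mu] * M[, nu])) / 1000, 0.2)
    }
  }
})

test_that("synthetic generation is reproducible and handles edge cases", {
  a <- generate_synthetic_patterns(6, 200, seed = 42)
  b <- generate_synthetic_patterns(6, 200, seed = 42)
  expect_identical(unclass(a), unclass(b))
  one <- generate_synthetic_patterns(1, 50, seed = 3)
  expect_equal(n_patterns(one), 1L)
  # infeasible: 5 patterns of length 4 all with |overlap| <= tiny bound
  expect_error(
    generate_synthetic_patterns(5, 4, max_abs_overlap = 0.1, seed = 1,
                                max_tries = 20),
    "best achieved")
})

test_that("pairwise overlap matrix matches direct dot products", {
  p1 <- c(1L, 1L, -1L, -1L)
  p2 <- c(1L, -1L, 1L, -1L)
  s <- memory_set(cbind(a = p1, b = p2, c = -p1))
  ov <- pairwise_overlap_matrix(s)
  expect_equal(diag(ov), c(a = 1, b = 1, c = 1))
  expect_equal(ov["a", "b"], 0)
  expect_equal(ov["a", "c"], -1)
  expect_equal(ov, t(ov))
})

test_that("glyph-like candidate pools have a correlated cluster and an independent rest", {
  pool <- generate_candidate_pool(n_independent = 10, n_correlated = 5,
                                  flip_fraction = 0.2, n_neurons = 1000,
                                  seed = 9)
  expect_equal(n_patterns(pool), 15L)
  ov <- pairwise_overlap_matrix(pool)
  cor_idx <- 11:15
  within_cluster <- ov[cor_idx, cor_idx][upper.tri(diag(5))]
  expect_gt(mean(within_cluster), 0.25) # ~ (1 - 2 * 0.2)^2
  ind_idx <- 1:10
  expect_lte(max(abs(ov[ind_idx, ind_idx][upper.tri(diag(10))])), 0.2)
})

test_that("optimal-subset selection minimizes collective correlation", {
  # k = candidate count: nothing to drop
  s <- random_set(5, 24, seed = 1)
  expect_identical(raw_mat(select_optimal_subset(s, 5)), raw_mat(s))

  # a duplicated pattern carries maximal burden and one copy is dropped;
  # exhaustive search over all (k-1)-subsets agrees
  set.seed(7)
  M <- matrix(sample(c(-1L, 1L), 24 * 6, replace = TRUE), 24, 6)
  M[, 6] <- M[, 1]
  colnames(M) <- paste0("p", 1:6)
  dup <- memory_set(M)
  opt <- select_optimal_subset(dup, 5)
  expect_length(intersect(c("p1", "p6"), colnames(opt)), 1L)
  best <- min(apply(utils::combn(6, 5), 2, function(ix) brute_subset_score(M, ix)))
  expect_equal(glance(opt)$score, best, tolerance = 1e-12)

  # the mutually correlated cluster of a glyph-like pool is broken up:
  # once its partners are gone a lone cluster member carries no excess
  # burden, so at most one survives
  pool <- generate_candidate_pool(n_independent = 12, n_correlated = 4,
                                  n_neurons = 600, seed = 2)
  opt2 <- select_optimal_subset(pool, 12)
  expect_lte(length(intersect(paste0("c", 13:16), colnames(opt2))), 1L)
})

test_that("greedy selection tracks exhaustive minimization on small pools", {
  # the greedy heuristic is deterministic and near-optimal: over seeded
  # small instances it attains the exhaustive optimum in the large
  # majority of cases and never trails it by much
  gaps <- vapply(1:60, function(seed) {
    set.seed(seed)
    n <- sample(6:10, 1)
    k <- sample(3:min(6, n - 1), 1)
    M <- matrix(sample(c(-1L, 1L), 12 * n, replace = TRUE), 12, n)
    colnames(M) <- paste0("p", seq_len(n))
    g <- select_optimal_subset(memory_set(M), k)
    best <- min(apply(utils::combn(n, k), 2,
                      function(ix) brute_subset_score(M, ix)))
    glance(g)$score - best
  }, numeric(1))
  expect_gte(mean(gaps < 1e-9), 0.85)
  expect_lte(max(gaps), 0.5)
})

test_that("optimal subsets beat random subsets of a 30-candidate pool", {
  pool <- generate_candidate_pool(n_neurons = 500, seed = 4)
  opt <- select_optimal_subset(pool, 20)
  opt_score <- glance(opt)$score
  set.seed(11)
  rand_scores <- replicate(100, {
    brute_subset_score(unclass(pool), sample.int(30, 20))
  })
  expect_true(all(opt_score <= rand_scores))
})

test_that("nonoptimal sets share exactly n_shared members with the optimal set", {
  pool <- generate_candidate_pool(n_neurons = 400, seed = 5)
  opt <- select_optimal_subset(pool, 20)

  same <- make_nonoptimal_set(opt, pool, n_shared = 20, seed = 1)
  expect_setequal(colnames(same), colnames(opt))

  non <- make_nonoptimal_set(opt, pool, n_shared = 15, seed = 1)
  expect_equal(n_patterns(non), 20L)
  expect_length(intersect(colnames(non), colnames(opt)), 15L)
  non2 <- make_nonoptimal_set(opt, pool, n_shared = 15, seed = 1)
  expect_identical(raw_mat(non), raw_mat(non2))

  # 30 candidates, 20 in the optimal set: at most 10 replacements possible
  expect_error(make_nonoptimal_set(opt, pool, n_shared = 5, seed = 1),
               "non-member")
})

test_that("cue corruption flips exactly round(level * n) pixels", {
  s <- generate_synthetic_patterns(1, 1000, seed = 6)
  p <- get_pattern(s, 1)

  expect_identical(as.integer(corrupt_cue(p, 0)), as.integer(p))
  expect_error(corrupt_cue(p, 0.6), "0.5")

  half <- corrupt_cue(p, 0.5, seed = 2)
  expect_equal(sum(as.integer(half) != as.integer(p)), 500L)

  a <- corrupt_cue(p, 0.05, seed = 3)
  b <- corrupt_cue(p, 0.05, seed = 3)
  expect_identical(as.integer(a), as.integer(b))

  # overlap identity over a grid of levels and lengths
  for (n in c(40, 333, 1000)) {
    q <- memory_pattern(rep(c(1L, -1L), length.out = n))
    for (lev in c(0, 0.1, 0.25, 0.37, 0.5)) {
      out <- corrupt_cue(q, lev, seed = 8)
      flipped <- round(lev * n)
      expect_equal(sum(as.integer(out) != as.integer(q)), flipped)
      expect_equal(state_overlap(out, q), 1 - 2 * flipped / n)
    }
  }
})
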