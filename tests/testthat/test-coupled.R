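test_that("sparse masks have an exact nonzero count", {
  expect_equal(sum(sparse_mask(10, 10, 0)), 0)
  expect_equal(sum(sparse_mask(10, 10, 1)), 100)
  m <- sparse_mask(200, 1000, 0.05, seed = 1)
  expect_equal(sum(m), 10000)
  expect_true(all(m %in% c(0, 1)))
  expect_identical(sparse_mask(50, 40, 0.13, seed = 2),
                   sparse_mask(50, 40, 0.13, seed = 2))
  expect_error(sparse_mask(5, 5, 1.2), "\\[0, 1\\]")
  # exact-to-one-entry over the reference density grid
  for (d in seq(0, 0.5, by = 0.05)) {
    expect_equal(sum(sparse_mask(60, 80, d, seed = 3)), round(d * 4800))
  }
})

test_that("interface matrix C carries ±1 weights on an exact sparse support", {
  C <- build_interface_C(200, 1000, 0.05, seed = 1)
  expect_equal(sum(C != 0), 10000)
  expect_true(all(C %in% c(-1, 0, 1)))
  expect_gt(sum(C == 1), 4000) # sign-balanced
  expect_identical(build_interface_C(20, 50, 0.2, seed = 9),
                   build_interface_C(20, 50, 0.2, seed = 9))
})

test_that("auxiliary patterns are the thresholded interface image of each memory", {
  mem <- random_set(4, 30, seed = 1)

  # zero interface: g(0) = +1 everywhere, degenerate and warned about
  expect_warning(aug0 <- derive_auxiliary_patterns(mem, matrix(0, 6, 30)),
                 "identical")
  expect_true(all(unclass(aug0$auxiliaries) == 1L))

  # a single +1 weight copies original neuron j into auxiliary neuron i
  C1 <- matrix(0, 6, 30)
  C1[3, 17] <- 1
  aug1 <- suppressWarnings(derive_auxiliary_patterns(mem, C1))
  expect_equal(unname(unclass(aug1$auxiliaries)[3, ]), unname(unclass(mem)[17, ]))

  # shape and pairing
  C <- build_interface_C(10, 30, 0.5, seed = 2)
  aug <- derive_auxiliary_patterns(mem, C)
  expect_equal(dim(unclass(aug$auxiliaries)), c(10L, 4L))
  expect_identical(colnames(aug$auxiliaries), colnames(mem))
  # brute-force: every auxiliary spin equals sign of the interface sum
  for (mu in 1:4) {
    m_o <- unclass(mem)[, mu]
    for (i in 1:10) {
      h <- sum(C[i, ] * m_o)
      expect_equal(unname(unclass(aug$auxiliaries)[i, mu]), if (h >= 0) 1L else -1L)
    }
  }
  expect_error(derive_auxiliary_patterns(mem, matrix(0, 4, 29)), "neurons")
})

test_that("feedback matrix B is the masked Hebbian cross-term", {
  mem <- random_set(1, 12, seed = 3)
  aux <- random_set(1, 5, seed = 4)
  expect_equal(build_feedback_B(mem, aux, 0), matrix(0, 12, 5))
  B <- build_feedback_B(mem, aux, 1)
  expect_equal(B, unclass(mem)[, 1, drop = FALSE] %*% t(unclass(aux)[, 1, drop = FALSE]))

  mem3 <- random_set(3, 12, seed = 5)
  aux3 <- random_set(3, 5, seed = 6)
  Bm <- build_feedback_B(mem3, aux3, 0.4, seed = 7)
  core <- unclass(mem3) %*% t(unclass(aux3))
  expect_equal(sum(Bm != 0 & Bm != core), 0) # nonzeros agree with the cross-term
  expect_lte(sum(Bm != 0), round(0.4 * 60)) # masked support (core may have zeros)
  expect_error(build_feedback_B(mem3, aux, 0.4), "one-to-one")
})

test_that("staged training produces consistent blocks and auxiliary attractors", {
  mem <- generate_synthetic_patterns(4, 200, seed = 8)
  net <- train_augmented_network(mem, n_aux = 60, density_C = 0.2,
                                 density_B = 0.3, seed = 8)
  expect_equal(dim(net$A), c(200L, 200L))
  expect_equal(dim(net$B), c(200L, 60L))
  expect_equal(dim(net$C), c(60L, 200L))
  expect_equal(dim(net$D), c(60L, 60L))
  expect_equal(net$stage, 5L)
  # stage 4: each auxiliary pattern a fixed point of D when near-orthogonal
  expect_true(all(net$aux_fixed_points))
  for (mu in 1:4) {
    m_a <- unclass(net$memories$auxiliaries)[, mu]
    expect_identical(update_state(unname(as.integer(m_a)), net$D), unname(as.integer(m_a)))
  }
  # control condition: zero feedback block
  net0 <- train_augmented_network(mem, n_aux = 60, density_C = 0.2,
                                  density_B = 0, seed = 8)
  expect_true(all(net0$B == 0))
})

test_that("toy staged training matches hand evaluation on an 8+4 system", {
  # two orthogonal memories over 8 neurons, dense interface
  m1 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  m2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  mem <- memory_set(cbind(a = m1, b = m2))
  net <- train_augmented_network(mem, n_aux = 4, density_C = 1,
                                 density_B = 1, seed = 1)
  # A: hand Hebbian
  expect_equal(net$A[1, 2], m1[1] * m1[2] + m2[1] * m2[2])
  expect_equal(net$A[1, 5], m1[1] * m1[5] + m2[1] * m2[5])
  # auxiliary patterns: g(C m_o) element by element
  for (mu in 1:2) {
    m_o <- unclass(mem)[, mu]
    for (i in 1:4) {
      expect_equal(unname(unclass(net$memories$auxiliaries)[i, mu]),
                   if (sum(net$C[i, ] * m_o) >= 0) 1L else -1L)
    }
  }
  # D: hand Hebbian on the recorded auxiliary patterns
  Ma <- unclass(net$memories$auxiliaries)
  Dh <- Ma %*% t(Ma)
  diag(Dh) <- 0
  expect_equal(net$D, Dh)
  # B at density 1: full cross-term
  expect_equal(net$B, unclass(mem) %*% t(Ma))
})

test_that("damage removes exactly the prescribed number of unordered pairs", {
  A <- hebbian_weights(random_set(5, 150, seed = 9))
  n_pairs <- sum(A[upper.tri(A)] != 0)

  expect_identical(inject_damage(A, 0), A)
  expect_true(all(inject_damage(A, 1) == 0))

  for (p in c(0.1, 0.3, 0.8)) {
    A_inj <- inject_damage(A, p, seed = 10)
    expect_equal(A_inj, t(A_inj)) # symmetry preserved
    left <- sum(A_inj[upper.tri(A_inj)] != 0)
    expect_equal(n_pairs - left, round(p * n_pairs))
    # only zeroing happened: surviving entries unchanged
    expect_true(all(A_inj[A_inj != 0] == A[A_inj != 0]))
  }
  # input not modified in place
  expect_equal(sum(A[upper.tri(A)] != 0), n_pairs)

  # asymmetric option lesions directed entries independently
  A_dir <- inject_damage(A, 0.5, seed = 11, symmetric = FALSE)
  n_dir <- sum(A != 0)
  expect_equal(n_dir - sum(A_dir != 0), round(0.5 * n_dir))
  expect_false(isSymmetric(A_dir))
})

test_that("recovery retrieves exact cues through an undamaged network", {
  mem <- generate_synthetic_patterns(5, 200, seed = 12)
  net <- train_augmented_network(mem, n_aux = 40, density_C = 0.2,
                                 density_B = 0.3, seed = 12)
  for (mu in 1:5) {
    res <- recover_memory(net, get_pattern(mem, mu))
    expect_true(res$converged)
    expect_true(is_retrieved(res$state, get_pattern(mem, mu)))
  }
  bad <- net
  bad$D <- NULL
  expect_error(recover_memory(bad, get_pattern(mem, 1)), "block D")
})

test_that("the staged recovery trace matches brute-force stage-by-stage evaluation", {
  mem <- memory_set(cbind(a = c(1, 1, 1, 1, -1, -1, -1, -1),
                          b = c(1, -1, 1, -1, 1, -1, 1, -1)))
  net <- train_augmented_network(mem, n_aux = 4, density_C = 1,
                                 density_B = 1, seed = 2)
  net_inj <- inject_damage(net, 0.4, seed = 3)
  cue <- corrupt_cue(get_pattern(mem, 1), 0.25, seed = 4)
  res <- recover_memory(net_inj, cue)

  # independent evaluation of every stage with naive loops
  st1 <- brute_converge(net_inj$A, as.integer(cue))
  expect_identical(res$trace$orig_stage1, st1$state)
  aux0 <- vapply(1:4, function(i) {
    if (sum(net_inj$C[i, ] * st1$state) >= 0) 1L else -1L
  }, integer(1))
  expect_identical(res$trace$aux_stage2, aux0)
  st4 <- brute_converge(net_inj$D, aux0)
  expect_identical(res$trace$aux_stage4, st4$state)
  field <- as.numeric(net_inj$B %*% st4$state)
  st5 <- brute_converge(net_inj$A, st1$state, bias = field)
  expect_identical(res$trace$orig_stage5, st5$state)
  expect_identical(res$state, st5$state)
})

test_that("only the stage-active blocks influence each recovery stage", {
  mem <- generate_synthetic_patterns(4, 120, seed = 13)
  net <- train_augmented_network(mem, n_aux = 24, density_C = 0.2,
                                 density_B = 0.4, seed = 13)
  net_inj <- inject_damage(net, 0.5, seed = 14)
  cue <- corrupt_cue(get_pattern(mem, 2), 0.2, seed = 15)
  base <- recover_memory(net_inj, cue)

  # perturbing B must not touch stages 1-4
  pert <- net_inj
  set.seed(16)
  pert$B <- matrix(sample(c(-3, 3), 120 * 24, replace = TRUE), 120, 24)
  out <- recover_memory(pert, cue)
  expect_identical(out$trace$orig_stage1, base$trace$orig_stage1)
  expect_identical(out$trace$aux_stage2, base$trace$aux_stage2)
  expect_identical(out$trace$aux_stage4, base$trace$aux_stage4)

  # perturbing C must not touch stage 1 or the final stage given the
  # same auxiliary state
  pert2 <- net_inj
  pert2$C <- -net_inj$C
  out2 <- recover_memory(pert2, cue)
  expect_identical(out2$trace$orig_stage1, base$trace$orig_stage1)

  # perturbing D must not touch stages 1-2
  pert3 <- net_inj
  pert3$D <- -net_inj$D
  out3 <- recover_memory(pert3, cue)
  expect_identical(out3$trace$orig_stage1, base$trace$orig_stage1)
  expect_identical(out3$trace$aux_stage2, base$trace$aux_stage2)
})

test_that("with zero feedback, recovery equals the damaged original network alone", {
  mem <- generate_synthetic_patterns(5, 150, seed = 17)
  net <- train_augmented_network(mem, n_aux = 30, density_C = 0.2,
                                 density_B = 0, seed = 17)
  net_inj <- inject_damage(net, 0.6, seed = 18)
  for (mu in 1:5) {
    cue <- corrupt_cue(get_pattern(mem, mu), 0.15, seed = mu)
    res <- recover_memory(net_inj, cue)
    alone <- run_to_convergence(cue, net_inj$A)
    expect_identical(res$state, alone$state)
  }
})

test_that("unclamped co-evolution and the hebbian interface variant run cleanly", {
  mem <- generate_synthetic_patterns(4, 100, seed = 19)
  net <- train_augmented_network(mem, n_aux = 20, density_C = 0.3,
                                 density_B = 0.3, seed = 19,
                                 c_weights = "hebbian")
  expect_true(any(net$C != 0))
  expect_true(all(net$C %in% round(net$C))) # masked integer cross-term
  res <- recover_memory(inject_damage(net, 0.3, seed = 20),
                        get_pattern(mem, 1), clamp = FALSE)
  expect_true(all(res$state %in% c(-1L, 1L)))
  expect_length(res$state, 100)
})
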