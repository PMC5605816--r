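#' Sparse binary mask with an exact nonzero count
#'
#' Places exactly `round(density * n_rows * n_cols)` ones at
#' seeded-uniform positions without replacement; all other entries are
#' zero. Used to sparsify the interface and feedback blocks.
#'
#' @param n_rows,n_cols mask dimensions.
#' @param density fraction of nonzero entries in \[0, 1\].
#' @param seed integer seed.
#' @return An `n_rows x n_cols` 0/1 matrix.
#' @export
sparse_mask <- function(n_rows, n_cols, density, seed = 1) {
  stopifnot_scalar_fraction(density, "density")
  n_total <- n_rows * n_cols
  n_on <- round(density * n_total)
  mask <- matrix(0, n_rows, n_cols)
  if (n_on > 0) {
    idx <- with_seed(seed, sample.int(n_total, n_on))
    mask[idx] <- 1
  }
  mask
}

#' Build the original-to-auxiliary interface matrix C
#'
#' C holds the sparse, novel connections through which the auxiliary
#' network reads original-network activity during calibration. Nonzero
#' positions come from a seeded [sparse_mask()]; their weights are
#' seeded-uniform ±1 by default (sign-balanced random weights give
#' near-orthogonal auxiliary codes for distinct memories).
#'
#' @param n_aux,n_orig auxiliary and original network sizes.
#' @param density interface density in (0, 1\] (default 0.05).
#' @param seed integer seed.
#' @return An `n_aux x n_orig` matrix of 0/±1 weights.
#' @export
build_interface_C <- function(n_aux, n_orig, density = 0.05, seed = 1) {
  mask <- sparse_mask(n_aux, n_orig, density, seed = derive_seed(seed, 101))
  signs <- with_seed(derive_seed(seed, 102),
                     matrix(sample(c(-1, 1), n_aux * n_orig, replace = TRUE),
                            n_aux, n_orig))
  mask * signs
}

#' Derive auxiliary memory patterns through the interface
#'
#' With the original network clamped at a stored memory `m_o`, inserting
#' the interface block drives each auxiliary neuron once:
#' `m_a = g(C %*% m_o)` (a single feedforward pass, no recurrent
#' settling). One auxiliary pattern is recorded per original memory.
#' A zero interface column sum yields spin +1 (`g(0) = +1`), so a zero C
#' degenerately maps every memory to the all-(+1) auxiliary pattern; a
#' warning is raised when derived auxiliary patterns collide.
#'
#' @param memories original [memory_set()].
#' @param C interface matrix from [build_interface_C()].
#' @return A list with `originals` and `auxiliaries` (both
#'   [memory_set()] objects, columns aligned by memory).
#' @export
derive_auxiliary_patterns <- function(memories, C) {
  M <- unclass(memories)
  if (ncol(C) != nrow(M)) {
    stop(sprintf("C has %d columns but memories have %d neurons",
                 ncol(C), nrow(M)), call. = FALSE)
  }
  A <- gain(C %*% M)
  storage.mode(A) <- "integer"
  colnames(A) <- colnames(M)
  if (anyDuplicated(t(A))) {
    warning("some auxiliary patterns are identical; the interface is too sparse or degenerate",
            call. = FALSE)
  }
  list(originals = memories,
       auxiliaries = memory_set(A, source = attr(memories, "source")))
}

#' Auxiliary network connectivity D
#'
#' Encodes the recorded auxiliary patterns in the auxiliary network by
#' the same Hebbian outer-product rule used for the original network.
#'
#' @param aux auxiliary [memory_set()].
#' @return Symmetric zero-diagonal weight matrix over auxiliary neurons.
#' @export
build_auxiliary_weights <- function(aux) {
  hebbian_weights(aux)
}

#' Auxiliary-to-original feedback matrix B
#'
#' The feedback block that lets the calibrated auxiliary network push a
#' damaged original network toward the correct memory. By default it
#' carries the Hebbian cross-term `sum_u m_o^u %*% t(m_a^u)` (the
#' off-diagonal block of the augmented outer product) restricted to a
#' seeded sparse mask; purely random feedback weights carry no memory
#' information and are available only for control experiments.
#'
#' @param memories original [memory_set()].
#' @param aux auxiliary [memory_set()] (same number of patterns).
#' @param density feedback density in \[0, 1\].
#' @param seed integer seed for the mask (and random weights, if used).
#' @param weights `"hebbian"` (default) or `"random"` ±1 weights.
#' @return An `n_orig x n_aux` matrix.
#' @export
build_feedback_B <- function(memories, aux, density, seed = 1,
                             weights = c("hebbian", "random")) {
  weights <- match.arg(weights)
  if (ncol(memories) != ncol(aux)) {
    stop("memories and auxiliary patterns must be paired one-to-one",
         call. = FALSE)
  }
  n_orig <- nrow(memories)
  n_aux <- nrow(aux)
  mask <- sparse_mask(n_orig, n_aux, density, seed = derive_seed(seed, 201))
  core <- if (weights == "hebbian") {
    tcrossprod(`storage.mode<-`(unclass(memories), "double"),
               `storage.mode<-`(unclass(aux), "double"))
  } else {
    with_seed(derive_seed(seed, 202),
              matrix(sample(c(-1, 1), n_orig * n_aux, replace = TRUE),
                     n_orig, n_aux))
  }
  mask * core
}

#' Train the coupled original + auxiliary network
#'
#' Runs the five-stage calibration protocol on a healthy original
#' network, before any damage:
#' \enumerate{
#'   \item original network alone: `A` from the Hebbian rule;
#'   \item interface inserted: build `C`, derive one auxiliary pattern
#'     per memory with the original clamped at each stored memory;
#'   \item auxiliary connectivity: `D` from the Hebbian rule on the
#'     recorded auxiliary patterns;
#'   \item interface withdrawn: verify each auxiliary pattern is a fixed
#'     point of the auxiliary dynamics under `D` alone (failures are
#'     reported in the result, not silently accepted);
#'   \item feedback inserted: build `B`.
#' }
#' At every stage only the blocks listed above are present; the returned
#' object is the stage-5 block system.
#'
#' @param memories original [memory_set()] (default geometry: 20
#'   patterns over 1000 neurons).
#' @param n_aux auxiliary network size (200 or 400 in the reference
#'   parameter grid; any positive count is accepted).
#' @param density_C interface density (default 0.05).
#' @param density_B feedback density in \[0, 0.5\] grid (any \[0,1\]
#'   accepted).
#' @param seed integer master seed for C, B masks and weights.
#' @param c_weights interface weight convention: `"random"` ±1 weights
#'   on the sparse mask (default), or `"hebbian"` — after the auxiliary
#'   patterns are derived with a provisional random interface, C is
#'   rebuilt as the masked Hebbian cross-term `sum_u m_a^u %*% t(m_o^u)`.
#' @param b_weights feedback convention passed to [build_feedback_B()].
#' @return A list of class `coupled_network` with blocks `A`, `B`, `C`,
#'   `D`, the `memories` (originals + auxiliaries), sizes, densities,
#'   `stage` (5 after training), `damage_level` (0), and
#'   `aux_fixed_points` (logical per memory: stage-4 verification).
#' @examples
#' mem <- generate_synthetic_patterns(4, 60, seed = 3)
#' net <- train_augmented_network(mem, n_aux = 12, density_C = 0.3, seed = 3)
#' all(net$aux_fixed_points)
#' @export
train_augmented_network <- function(memories, n_aux = 200, density_C = 0.05,
                                    density_B = 0.25, seed = 1,
                                    c_weights = c("random", "hebbian"),
                                    b_weights = c("hebbian", "random")) {
  c_weights <- match.arg(c_weights)
  b_weights <- match.arg(b_weights)
  n_orig <- nrow(memories)

  # stage 1: the healthy original network
  A <- hebbian_weights(memories)

  # stage 2: insert the interface, record auxiliary patterns
  C <- build_interface_C(n_aux, n_orig, density_C, seed = seed)
  aug <- derive_auxiliary_patterns(memories, C)
  if (c_weights == "hebbian") {
    mask <- sparse_mask(n_aux, n_orig, density_C, seed = derive_seed(seed, 101))
    C <- mask * tcrossprod(`storage.mode<-`(unclass(aug$auxiliaries), "double"),
                           `storage.mode<-`(unclass(memories), "double"))
  }

  # stage 3: encode the auxiliary patterns
  D <- build_auxiliary_weights(aug$auxiliaries)

  # stage 4: interface withdrawn; check the auxiliary attractors
  aux_fp <- vapply(seq_len(ncol(aug$auxiliaries)), function(mu) {
    m_a <- unclass(aug$auxiliaries)[, mu]
    identical(gain(drop(D %*% m_a)), as.integer(m_a))
  }, logical(1))

  # stage 5: insert the feedback block
  B <- build_feedback_B(memories, aug$auxiliaries, density_B,
                        seed = seed, weights = b_weights)

  structure(list(A = A, B = B, C = C, D = D,
                 memories = aug,
                 n_orig = n_orig, n_aux = n_aux,
                 density_C = density_C, density_B = density_B,
                 c_weights = c_weights, b_weights = b_weights,
                 seed = seed, stage = 5L, damage_level = 0,
                 aux_fixed_points = aux_fp),
            class = "coupled_network")
}

#' @export
print.coupled_network <- function(x, ...) {
  cat(sprintf(paste0("<coupled_network: %d original + %d auxiliary neurons, ",
                     "%d memories>\n"),
              x$n_orig, x$n_aux, ncol(x$memories$originals)))
  cat(sprintf("  density_C = %.2f, density_B = %.2f, damage = %.0f%%\n",
              x$density_C, x$density_B, 100 * x$damage_level))
  cat(sprintf("  auxiliary fixed points: %d/%d\n",
              sum(x$aux_fixed_points), length(x$aux_fixed_points)))
  invisible(x)
}

#' Inject random connectivity damage (virtual lesions)
#'
#' Randomly eliminates a fraction `level` of the network's connections
#' by zeroing weights, modelling axonal swellings, axotomies or cell
#' death that block information flow. A connection is an unordered
#' neuron pair: with `symmetric = TRUE` (default) exactly
#' `round(level * n_pairs)` currently nonzero off-diagonal pairs
#' `{i, j}` are zeroed on both sides, preserving symmetry; with
#' `symmetric = FALSE` directed entries are lesioned independently.
#' The input matrix is not modified.
#'
#' @param A weight matrix (or a `coupled_network`, whose `A` block is
#'   lesioned).
#' @param level fraction of connections removed, `p` in \[0, 1\]
#'   (reference grid: 0 to 0.8).
#' @param seed integer seed selecting the lesion topology.
#' @param symmetric lesion unordered pairs (default) or directed edges.
#' @return The lesioned matrix `A_inj`, or the network with `A`
#'   replaced by `A_inj` and `damage_level` recorded.
#' @export
inject_damage <- function(A, level, seed = 1, symmetric = TRUE) {
  stopifnot_scalar_fraction(level, "level")
  if (inherits(A, "coupled_network")) {
    net <- A
    net$A <- inject_damage(net$A, level, seed = seed, symmetric = symmetric)
    net$damage_level <- level
    net$damage_seed <- seed
    return(net)
  }
  A_inj <- A
  if (symmetric) {
    nz <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    n_kill <- round(level * nrow(nz))
    if (n_kill > 0) {
      pick <- with_seed(seed, sample.int(nrow(nz), n_kill))
      ij <- nz[pick, , drop = FALSE]
      A_inj[ij] <- 0
      A_inj[ij[, c(2, 1), drop = FALSE]] <- 0
    }
  } else {
    nz <- which(A != 0 & row(A) != col(A))
    n_kill <- round(level * length(nz))
    if (n_kill > 0) {
      pick <- with_seed(seed, sample(nz, n_kill))
      A_inj[pick] <- 0
    }
  }
  A_inj
}

#' Staged memory recovery in a damaged coupled network
#'
#' Runs the five-stage recovery protocol from a (possibly noisy) cue:
#' \enumerate{
#'   \item damaged original network alone (`A_inj`): the cue runs to
#'     convergence;
#'   \item interface activated: the auxiliary network is initialized
#'     from the converged original state, `S_a = g(C %*% S_o)`;
#'   \item,4. auxiliary network converges under `D` with the original
#'     clamped, retrieving the auxiliary memory;
#'   \item feedback activated (interface severed): the original network
#'     re-converges under `A_inj` with the constant auxiliary field
#'     `B %*% S_a` added to every potential, the auxiliary clamped at
#'     its converged state.
#' }
#' With `clamp = FALSE` the two populations co-evolve: stages 3-4 update
#' original and auxiliary jointly under the stage-3 block structure, and
#' stage 5 updates them jointly under the stage-5 blocks.
#'
#' @param net a trained (and typically damaged) `coupled_network`.
#' @param cue ±1 vector of length `n_orig` (a corrupted memory).
#' @param config a [dynamics_config()].
#' @param clamp clamp the passive population at each stage (default).
#' @return A list with `state` (final original ±1 vector), `converged`
#'   (stage-5 convergence flag), and `trace`: the state after each
#'   stage (`orig_stage1`, `aux_stage2`, `aux_stage4`, `orig_stage5`)
#'   plus per-stage convergence flags.
#' @export
recover_memory <- function(net, cue, config = dynamics_config(),
                           clamp = TRUE) {
  for (blk in c("A", "B", "C", "D")) {
    if (is.null(net[[blk]])) {
      stop(sprintf("network is missing block %s; train it first", blk),
           call. = FALSE)
    }
  }
  if (length(cue) != net$n_orig) {
    stop(sprintf("cue length %d does not match the original network size %d",
                 length(cue), net$n_orig), call. = FALSE)
  }

  # stage inj1: damaged original alone
  r1 <- run_to_convergence(cue, net$A, config)
  s_orig <- r1$state

  # stage inj2: interface on, auxiliary initialized from original activity
  s_aux0 <- gain(drop(net$C %*% as.numeric(s_orig)))

  if (clamp) {
    # stages inj3-inj4: auxiliary converges under D, original clamped
    r4 <- run_to_convergence(s_aux0, net$D, config)
    s_aux <- r4$state
    # stage inj5: feedback on, original re-converges under A_inj + B field
    field <- drop(net$B %*% as.numeric(s_aux))
    r5 <- run_to_convergence(s_orig, net$A, config, bias = field)
    list(state = r5$state, converged = r5$converged,
         trace = list(orig_stage1 = s_orig, aux_stage2 = s_aux0,
                      aux_stage4 = s_aux, orig_stage5 = r5$state,
                      converged_stage1 = r1$converged,
                      converged_stage4 = r4$converged,
                      converged_stage5 = r5$converged))
  } else {
    # unclamped co-evolution on the joint state
    n_o <- net$n_orig
    n_a <- net$n_aux
    W3 <- rbind(cbind(net$A, matrix(0, n_o, n_a)), cbind(net$C, net$D))
    r4 <- run_to_convergence(c(s_orig, s_aux0), W3, config)
    s_aux <- r4$state[(n_o + 1):(n_o + n_a)]
    W5 <- rbind(cbind(net$A, net$B),
                cbind(matrix(0, n_a, n_o), net$D))
    r5 <- run_to_convergence(c(r4$state[seq_len(n_o)], s_aux), W5, config)
    list(state = r5$state[seq_len(n_o)], converged = r5$converged,
         trace = list(orig_stage1 = s_orig, aux_stage2 = s_aux0,
                      aux_stage4 = s_aux,
                      orig_stage5 = r5$state[seq_len(n_o)],
                      converged_stage1 = r1$converged,
                      converged_stage4 = r4$converged,
                      converged_stage5 = r5$converged))
  }
}
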