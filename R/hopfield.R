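#' Hebbian outer-product weight matrix
#'
#' Builds the Hopfield connectivity `W = M %*% t(M)` summed over the
#' stored patterns, with the diagonal set to zero so that the input
#' potential `h = W %*% S` realizes the `j != i` exclusion as a single
#' matrix product. Entries are integers for ±1 patterns, bounded in
#' magnitude by the number of stored patterns, and the matrix is
#' symmetric. No `1/n` normalization is applied: the sign gain function
#' makes the dynamics invariant to any positive rescaling of `W`.
#'
#' @param memories a [memory_set()] (patterns in columns).
#' @return An `n x n` symmetric numeric matrix with zero diagonal.
#' @examples
#' s <- generate_synthetic_patterns(3, 50, seed = 1)
#' W <- hebbian_weights(s)
#' max(abs(W)) <= n_patterns(s)
#' @export
hebbian_weights <- function(memories) {
  M <- unclass(memories)
  if (is.null(dim(M))) M <- matrix(as.integer(M), ncol = 1)
  storage.mode(M) <- "double"
  W <- tcrossprod(M)
  diag(W) <- 0
  W
}

#' Input potential of every neuron
#'
#' `h_i = sum_{j != i} w_ij S_j`, computed as `W %*% S` (valid because
#' the Hebbian construction zeroes the diagonal).
#'
#' @param state ±1 spin vector.
#' @param weights square weight matrix with zero diagonal.
#' @return Numeric vector of potentials.
#' @export
input_potential <- function(state, weights) {
  if (length(state) != ncol(weights)) {
    stop(sprintf("state length %d does not match weight matrix dimension %d",
                 length(state), ncol(weights)), call. = FALSE)
  }
  drop(weights %*% as.numeric(state))
}

#' Sign-threshold gain function
#'
#' `g(x) = +1` for `x >= 0` and `-1` for `x < 0`. Zero input maps to +1;
#' there is no stochastic tie-break. Vectorized.
#'
#' @param x numeric vector of input potentials.
#' @return Integer vector of ±1 spins.
#' @export
gain <- function(x) {
  ifelse(x >= 0, 1L, -1L)
}

#' Dynamics configuration
#'
#' @param update_mode `"synchronous"` (all spins replaced by
#'   `g(h_i)` simultaneously — the default, matching the one-step map
#'   `S(t+1) = g(W S(t))`) or `"asynchronous"` (one sweep updates each
#'   neuron once, in seeded random order, each potential recomputed from
#'   the partially updated state; guarantees non-increasing energy).
#' @param max_sweeps iteration cap (default 50 full sweeps).
#' @param cycle_detection detect period-2 cycles of the synchronous map
#'   and stop early, reporting non-convergence.
#' @param seed seed for the asynchronous update order.
#' @param record_energy record the energy after every elementary update
#'   (per sweep in synchronous mode, per spin flip in asynchronous
#'   mode); retrieved from the result's `energy_trace`.
#' @return A list of class `dynamics_config`.
#' @export
dynamics_config <- function(update_mode = c("synchronous", "asynchronous"),
                            max_sweeps = 50, cycle_detection = TRUE,
                            seed = 1, record_energy = FALSE) {
  update_mode <- match.arg(update_mode)
  if (max_sweeps < 1) stop("max_sweeps must be >= 1", call. = FALSE)
  structure(list(update_mode = update_mode, max_sweeps = max_sweeps,
                 cycle_detection = cycle_detection, seed = seed,
                 record_energy = record_energy),
            class = "dynamics_config")
}

#' One update sweep of the network state
#'
#' Synchronous mode applies `S <- g(W S + bias)` to all neurons at once;
#' asynchronous mode visits every neuron once in a seeded random order,
#' recomputing each potential from the current (partially updated)
#' state.
#'
#' @param state ±1 spin vector.
#' @param weights square weight matrix, zero diagonal.
#' @param config a [dynamics_config()].
#' @param bias optional constant external field added to every
#'   potential (used when another, clamped population feeds this one).
#' @param sweep_index sweep counter used to vary the asynchronous order
#'   between sweeps under one seed.
#' @return Updated ±1 integer spin vector.
#' @export
update_state <- function(state, weights, config = dynamics_config(),
                         bias = NULL, sweep_index = 1) {
  n <- length(state)
  if (n != ncol(weights)) {
    stop("state/weights dimension mismatch", call. = FALSE)
  }
  b <- if (is.null(bias)) 0 else bias
  if (config$update_mode == "synchronous") {
    gain(drop(weights %*% as.numeric(state)) + b)
  } else {
    order <- with_seed(derive_seed(config$seed, sweep_index),
                       sample.int(n))
    s <- as.numeric(state)
    bb <- if (length(b) == 1L) rep(b, n) else b
    for (i in order) {
      h <- sum(weights[i, ] * s) + bb[i]
      s[i] <- if (h >= 0) 1 else -1
    }
    as.integer(s)
  }
}

#' Iterate the dynamics to a fixed point
#'
#' Repeats update sweeps until the state repeats its previous value (a
#' fixed point), a period-2 cycle of the synchronous map is detected
#' (reported as not converged), or `max_sweeps` is exhausted.
#'
#' @inheritParams update_state
#' @param initial starting ±1 spin vector (the retrieval cue).
#' @return A list with elements `state` (final ±1 vector), `converged`
#'   (logical), `sweeps` (sweeps used), `cycle` (logical: a period-2
#'   cycle was detected) and, if requested, `energy_trace`.
#' @examples
#' s <- generate_synthetic_patterns(2, 64, seed = 2)
#' W <- hebbian_weights(s)
#' out <- run_to_convergence(get_pattern(s, 1), W)
#' out$converged
#' @export
run_to_convergence <- function(initial, weights, config = dynamics_config(),
                               bias = NULL) {
  s <- as.integer(initial)
  prev2 <- NULL
  energies <- if (config$record_energy) energy(s, weights) else NULL
  for (sweep in seq_len(config$max_sweeps)) {
    if (config$record_energy && config$update_mode == "asynchronous") {
      step <- async_sweep_with_energy(s, weights, config, bias, sweep)
      s_new <- step$state
      energies <- c(energies, step$energies)
    } else {
      s_new <- update_state(s, weights, config, bias, sweep)
      if (config$record_energy) energies <- c(energies, energy(s_new, weights))
    }
    if (identical(s_new, s)) {
      return(list(state = s_new, converged = TRUE, sweeps = sweep,
                  cycle = FALSE, energy_trace = energies))
    }
    if (config$cycle_detection && config$update_mode == "synchronous" &&
        !is.null(prev2) && identical(s_new, prev2)) {
      return(list(state = s_new, converged = FALSE, sweeps = sweep,
                  cycle = TRUE, energy_trace = energies))
    }
    prev2 <- s
    s <- s_new
  }
  list(state = s, converged = FALSE, sweeps = config$max_sweeps,
       cycle = FALSE, energy_trace = energies)
}

# Asynchronous sweep that records the energy after every single-spin
# update (used by the Lyapunov diagnostics).
async_sweep_with_energy <- function(state, weights, config, bias, sweep_index) {
  n <- length(state)
  order <- with_seed(derive_seed(config$seed, sweep_index), sample.int(n))
  s <- as.numeric(state)
  b <- if (is.null(bias)) rep(0, n) else rep_len(bias, n)
  energies <- numeric(n)
  for (k in seq_along(order)) {
    i <- order[k]
    h <- sum(weights[i, ] * s) + b[i]
    s[i] <- if (h >= 0) 1 else -1
    energies[k] <- -0.5 * sum(s * drop(weights %*% s))
  }
  list(state = as.integer(s), energies = energies)
}

#' Hopfield energy of a state
#'
#' The classical Lyapunov function `E = -1/2 * t(S) W S`. Under
#' asynchronous single-spin updates with symmetric zero-diagonal
#' weights, E never increases, which makes it a convergence diagnostic.
#'
#' @param state ±1 spin vector.
#' @param weights symmetric weight matrix.
#' @return Scalar energy.
#' @export
energy <- function(state, weights) {
  if (!isSymmetric(unname(weights))) {
    stop("energy requires a symmetric weight matrix", call. = FALSE)
  }
  s <- as.numeric(state)
  -0.5 * sum(s * drop(weights %*% s))
}

#' Normalized overlap between a state and a pattern
#'
#' `(S . m) / n`, in \[-1, 1\]: 1 means exact retrieval, -1 retrieval of
#' the negated pattern, and a state differing in a fraction `f` of spins
#' has overlap `1 - 2f`.
#'
#' @param state ±1 spin vector.
#' @param pattern ±1 pattern of the same length.
#' @return Scalar overlap.
#' @export
state_overlap <- function(state, pattern) {
  if (length(state) != length(pattern)) {
    stop("state and pattern lengths differ", call. = FALSE)
  }
  sum(as.numeric(state) * as.numeric(pattern)) / length(state)
}

#' Exact-match retrieval test
#'
#' A memory counts as retrieved only when the state equals the stored
#' pattern exactly (overlap 1); convergence to the negated pattern does
#' not count.
#'
#' @inheritParams state_overlap
#' @return Logical.
#' @export
is_retrieved <- function(state, pattern) {
  if (length(state) != length(pattern)) {
    stop("state and pattern lengths differ", call. = FALSE)
  }
  all(as.integer(state) == as.integer(pattern))
}
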