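# Independent brute-force oracles. Deliberately naive (explicit loops,
# explicit j != i sums) so they share no code path with the package.

# one synchronous step: S_i' = sign(sum_{j != i} w_ij S_j), sign(0) = +1
brute_sync_step <- function(W, s) {
  n <- length(s)
  out <- integer(n)
  for (i in seq_len(n)) {
    h <- 0
    for (j in seq_len(n)) if (j != i) h <- h + W[i, j] * s[j]
    out[i] <- if (h >= 0) 1L else -1L
  }
  out
}

# one asynchronous sweep in the given visit order, potentials recomputed
# from the partially updated state
brute_async_sweep <- function(W, s, order, bias = rep(0, length(s))) {
  for (i in order) {
    h <- bias[i]
    for (j in seq_along(s)) if (j != i) h <- h + W[i, j] * s[j]
    s[i] <- if (h >= 0) 1L else -1L
  }
  as.integer(s)
}

# iterate synchronous steps to a fixed point (or give up)
brute_converge <- function(W, s, bias = rep(0, length(s)), max_sweeps = 50) {
  for (sweep in seq_len(max_sweeps)) {
    s_new <- integer(length(s))
    for (i in seq_along(s)) {
      h <- bias[i]
      for (j in seq_along(s)) if (j != i) h <- h + W[i, j] * s[j]
      s_new[i] <- if (h >= 0) 1L else -1L
    }
    if (all(s_new == s)) return(list(state = s_new, converged = TRUE))
    s <- s_new
  }
  list(state = s, converged = FALSE)
}

# every ±1 state of an n-neuron network, one per row
all_states <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  dimnames(grid) <- NULL
  grid
}

# Walsh-Hadamard rows: 2^k mutually orthogonal ±1 patterns of length 2^k
hadamard_patterns <- function(k) {
  H <- matrix(1L)
  for (i in seq_len(k)) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

# collective correlation score, recomputed naively
brute_subset_score <- function(M, idx) {
  s <- 0
  n <- nrow(M)
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a < b) s <- s + abs(sum(M[, idx[a]] * M[, idx[b]]) / n)
    }
  }
  s
}

# pattern matrix stripped of class/source attributes, for comparisons
raw_mat <- function(s) {
  m <- unclass(s)
  attr(m, "source") <- NULL
  m
}

# small random memory set for fixtures
random_set <- function(k, n, seed) {
  set.seed(seed)
  M <- matrix(sample(c(-1L, 1L), n * k, replace = TRUE), n, k)
  colnames(M) <- paste0("p", seq_len(k))
  memory_set(M)
}
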