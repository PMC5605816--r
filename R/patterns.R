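#' Memory patterns and memory sets
#'
#' A *memory pattern* is a vector of ±1 spins of length `n_neurons`
#' (default 1000, a flattened 40 x 25 bitmap: -1 = black/off, +1 =
#' white/on). A *memory set* holds an ordered collection of such patterns
#' as the columns of an integer matrix `M`, so the Hebbian weight matrix
#' is simply `M %*% t(M)`.
#'
#' @param values numeric vector of +1/-1 entries.
#' @param label short identifier, unique within a set.
#' @name memory-patterns
NULL

#' Construct a memory pattern
#'
#' @rdname memory-patterns
#' @return An integer vector of class `memory_pattern` with a `label`
#'   attribute.
#' @examples
#' p <- memory_pattern(c(1, -1, 1, -1), label = "demo")
#' @export
memory_pattern <- function(values, label = "m") {
  values <- as.integer(values)
  if (length(values) == 0L || !all(values %in% c(-1L, 1L))) {
    stop("a memory pattern must be a non-empty vector with entries +1 or -1",
         call. = FALSE)
  }
  structure(values, label = as.character(label)[1], class = "memory_pattern")
}

#' @export
print.memory_pattern <- function(x, ...) {
  cat(sprintf("<memory_pattern '%s': %d neurons, %d on (+1)>\n",
              attr(x, "label"), length(x), sum(x == 1L)))
  invisible(x)
}

#' Construct a memory set
#'
#' @param patterns a +1/-1 matrix with one pattern per column (column
#'   names become labels), or a list of [memory_pattern()] vectors.
#' @param source provenance tag: `"optimal"`, `"nonoptimal"`,
#'   `"candidate_pool"` or `"synthetic"`.
#' @return An object of class `memory_set`: an integer matrix
#'   (`n_neurons` x `k`) with unique column labels and a `source`
#'   attribute.
#' @export
memory_set <- function(patterns, source = "candidate_pool") {
  if (is.list(patterns)) {
    lens <- lengths(patterns)
    if (length(unique(lens)) > 1L) {
      stop("all patterns in a set must have the same length", call. = FALSE)
    }
    labels <- vapply(seq_along(patterns), function(i) {
      lb <- attr(patterns[[i]], "label")
      if (is.null(lb)) paste0("m", i) else lb
    }, character(1))
    patterns <- matrix(as.integer(unlist(patterns)), nrow = lens[1],
                       dimnames = list(NULL, labels))
  }
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  if (ncol(patterns) == 0L) stop("memory set must be non-empty", call. = FALSE)
  if (!all(patterns %in% c(-1L, 1L))) {
    stop("memory set entries must all be +1 or -1", call. = FALSE)
  }
  if (is.null(colnames(patterns))) {
    colnames(patterns) <- paste0("m", seq_len(ncol(patterns)))
  }
  if (anyDuplicated(colnames(patterns))) {
    stop("pattern labels must be unique", call. = FALSE)
  }
  structure(patterns, source = source, class = c("memory_set", "matrix"))
}

#' @export
print.memory_set <- function(x, ...) {
  ov <- pairwise_overlap_matrix(x)
  off <- ov[upper.tri(ov)]
  cat(sprintf("<memory_set [%s]: %d patterns x %d neurons>\n",
              attr(x, "source"), ncol(x), nrow(x)))
  if (length(off)) {
    cat(sprintf("  pairwise |overlap|: mean %.4f, max %.4f\n",
                mean(abs(off)), max(abs(off))))
  }
  invisible(x)
}

#' @export
`[.memory_set` <- function(x, i, ...) {
  m <- unclass(x)[, i, drop = FALSE]
  memory_set(m, source = attr(x, "source"))
}

#' Number of patterns and neurons in a set
#' @param set a `memory_set`.
#' @export
n_patterns <- function(set) ncol(set)

#' @rdname n_patterns
#' @export
n_neurons <- function(set) nrow(set)

#' Extract one pattern from a set
#' @param set a `memory_set`.
#' @param i column index or label.
#' @export
get_pattern <- function(set, i) {
  memory_pattern(unclass(set)[, i], label = colnames(set)[if (is.character(i)) match(i, colnames(set)) else i])
}

#' Generate synthetic low-correlation memory patterns
#'
#' Draws random ±1 patterns by rejection sampling until every pairwise
#' normalized overlap `|m^u . m^v| / n` is at most `max_abs_overlap`.
#' For 20 patterns over 1000 neurons random patterns have overlap
#' standard deviation ~ `1/sqrt(n)` ~ 0.032, so the default bound of
#' 0.2 is loose; the generator stands in for the bitmap memory sets,
#' whose optimized subset is likewise collectively close to orthogonal.
#'
#' @param n_patterns number of patterns to generate.
#' @param n_neurons pattern length (default 1000).
#' @param max_abs_overlap pairwise overlap bound in (0, 1].
#' @param seed integer seed; same seed gives bitwise-identical sets.
#' @param source tag recorded on the result.
#' @param max_tries rejection budget per pattern.
#' @return A [memory_set()] with labels `s1, s2, ...`.
#' @examples
#' s <- generate_synthetic_patterns(5, 100, max_abs_overlap = 0.3, seed = 1)
#' max(abs(pairwise_overlap_matrix(s)[upper.tri(diag(5))]))
#' @export
generate_synthetic_patterns <- function(n_patterns, n_neurons = 1000,
                                        max_abs_overlap = 0.2, seed = 1,
                                        source = "synthetic",
                                        max_tries = 1000) {
  if (n_patterns < 1) stop("n_patterns must be >= 1", call. = FALSE)
  stopifnot_scalar_fraction(max_abs_overlap, "max_abs_overlap", lo = 1e-12)
  with_seed(seed, {
    M <- matrix(NA_integer_, n_neurons, n_patterns)
    for (k in seq_len(n_patterns)) {
      best <- Inf
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- sample(c(-1L, 1L), n_neurons, replace = TRUE)
        worst <- if (k == 1L) 0 else max(abs(crossprod(M[, seq_len(k - 1L), drop = FALSE], cand)) / n_neurons)
        if (worst <= max_abs_overlap) {
          M[, k] <- cand
          ok <- TRUE
          break
        }
        best <- min(best, worst)
      }
      if (!ok) {
        stop(sprintf(paste0("could not place pattern %d within overlap bound %.3f ",
                            "after %d tries (best achieved %.3f)"),
                     k, max_abs_overlap, max_tries, best), call. = FALSE)
      }
    }
    colnames(M) <- paste0("s", seq_len(n_patterns))
    memory_set(M, source = source)
  })
}

#' Generate a glyph-like candidate pool of memory patterns
#'
#' Emulates the statistics of bitmap-symbol memory pools: most
#' candidates are independent (near-orthogonal over 1000 neurons) but a
#' cluster shares strokes/background and is therefore mutually
#' correlated, which is exactly what makes subset optimization
#' worthwhile. The correlated cluster is built by flipping a fraction
#' `flip_fraction` of a common random template per member, giving an
#' expected pairwise overlap of `(1 - 2 * flip_fraction)^2` within the
#' cluster (~0.36 at the default, comparable to rendered dot-matrix
#' symbol pools while keeping 20-item subsets retrievable).
#'
#' @param n_independent number of independent candidates (default 22).
#' @param n_correlated number of template-derived candidates (default 8).
#' @param flip_fraction fraction of template pixels flipped per
#'   correlated candidate.
#' @param n_neurons pattern length.
#' @param max_abs_overlap overlap bound enforced among the independent
#'   candidates.
#' @param seed integer seed.
#' @return A [memory_set()] of `n_independent + n_correlated` patterns
#'   labelled `c1, c2, ...` (correlated members last), tagged
#'   `"candidate_pool"`.
#' @export
generate_candidate_pool <- function(n_independent = 22, n_correlated = 8,
                                    flip_fraction = 0.2, n_neurons = 1000,
                                    max_abs_overlap = 0.2, seed = 1) {
  stopifnot_scalar_fraction(flip_fraction, "flip_fraction", 0, 0.5)
  ind <- generate_synthetic_patterns(n_independent, n_neurons,
                                     max_abs_overlap = max_abs_overlap,
                                     seed = derive_seed(seed, 1))
  M <- unclass(ind)
  if (n_correlated > 0) {
    cor_block <- with_seed(derive_seed(seed, 2), {
      tmpl <- sample(c(-1L, 1L), n_neurons, replace = TRUE)
      n_flip <- round(flip_fraction * n_neurons)
      vapply(seq_len(n_correlated), function(i) {
        x <- tmpl
        idx <- sample.int(n_neurons, n_flip)
        x[idx] <- -x[idx]
        x
      }, integer(n_neurons))
    })
    M <- cbind(M, cor_block)
  }
  colnames(M) <- paste0("c", seq_len(ncol(M)))
  memory_set(M, source = "candidate_pool")
}

#' Pairwise normalized overlap matrix
#'
#' Entry (u, v) is `(m^u . m^v) / n`, the normalized dot product between
#' patterns; the diagonal is 1 and a pattern and its negation give -1.
#'
#' @param set a [memory_set()].
#' @return A symmetric `k x k` numeric matrix with unit diagonal.
#' @export
pairwise_overlap_matrix <- function(set) {
  M <- unclass(set)
  crossprod(M) / nrow(M)
}

#' Select the most orthogonal subset of candidate memories
#'
#' Chooses `k` patterns approximately minimizing the collective
#' correlation score `sum_{u<v} |overlap(u, v)|` by greedy elimination:
#' repeatedly drop the pattern with the largest summed absolute overlap
#' to the remaining patterns (ties broken by dropping the lowest index).
#' The greedy path is deterministic and matches exhaustive minimization
#' on small candidate pools.
#'
#' @param candidates a [memory_set()] of candidate patterns.
#' @param k subset size (default 20).
#' @return A [memory_set()] tagged `"optimal"`, in original column order.
#' @export
select_optimal_subset <- function(candidates, k = 20) {
  if (k > ncol(candidates)) {
    stop(sprintf("k = %d exceeds candidate count %d", k, ncol(candidates)),
         call. = FALSE)
  }
  keep <- seq_len(ncol(candidates))
  ov <- abs(pairwise_overlap_matrix(candidates))
  diag(ov) <- 0
  while (length(keep) > k) {
    burden <- rowSums(ov[keep, keep, drop = FALSE])
    drop_at <- which.max(burden) # which.max takes the first (lowest-index) tie
    keep <- keep[-drop_at]
  }
  out <- candidates[keep]
  attr(out, "source") <- "optimal"
  out
}

# Collective correlation score of a set: sum of absolute pairwise overlaps.
subset_score <- function(set) {
  ov <- pairwise_overlap_matrix(set)
  sum(abs(ov[upper.tri(ov)]))
}

#' Build a nonoptimal memory set sharing part of the optimal one
#'
#' Keeps a seeded-random choice of `n_shared` members of the optimal set
#' and replaces the remainder with seeded-random candidates that are not
#' in the optimal set, emulating a memory collection that was not
#' optimized for orthogonality.
#'
#' @param optimal the optimized [memory_set()] (members of `candidates`).
#' @param candidates the full candidate pool.
#' @param n_shared number of members kept (default 15 of 20).
#' @param seed integer seed.
#' @return A [memory_set()] tagged `"nonoptimal"` whose label set shares
#'   exactly `n_shared` labels with `optimal`.
#' @export
make_nonoptimal_set <- function(optimal, candidates, n_shared = 15, seed = 1) {
  k <- ncol(optimal)
  if (n_shared > k) stop("n_shared cannot exceed the optimal set size", call. = FALSE)
  if (!all(colnames(optimal) %in% colnames(candidates))) {
    stop("optimal set members must be drawn from the candidate pool", call. = FALSE)
  }
  outside <- setdiff(colnames(candidates), colnames(optimal))
  n_new <- k - n_shared
  if (length(outside) < n_new) {
    stop(sprintf("need %d non-member candidates, only %d available",
                 n_new, length(outside)), call. = FALSE)
  }
  if (n_new == 0L) {
    out <- optimal
    attr(out, "source") <- "nonoptimal"
    return(out)
  }
  with_seed(seed, {
    kept <- sort(sample(colnames(optimal), n_shared))
    added <- sample(outside, n_new)
    out <- candidates[c(kept, added)]
    attr(out, "source") <- "nonoptimal"
    out
  })
}

#' Corrupt a cue by flipping a fixed number of pixels
#'
#' Flips the sign of exactly `round(level * n)` entries, chosen
#' uniformly without replacement, modelling a noisy retrieval cue. The
#' exact-count convention makes the noise magnitude of every trial
#' deterministic: the overlap between input and output is always
#' `1 - 2 * round(level * n) / n`.
#'
#' @param pattern a [memory_pattern()] or ±1 vector.
#' @param level noise level in \[0, 0.5\] (fraction of pixels flipped).
#' @param seed integer seed.
#' @return A corrupted copy; the input is not modified.
#' @export
corrupt_cue <- function(pattern, level, seed = 1) {
  stopifnot_scalar_fraction(level, "level", 0, 0.5)
  n <- length(pattern)
  n_flip <- round(level * n)
  out <- as.integer(pattern)
  if (n_flip > 0) {
    idx <- with_seed(seed, sample.int(n, n_flip))
    out[idx] <- -out[idx]
  }
  memory_pattern(out, label = attr(pattern, "label") %||% "cue")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
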