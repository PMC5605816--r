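# broom-style accessors for fitted/simulated objects.

#' @export
tidy.sweep_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "config") <- NULL
  class(out) <- setdiff(class(out), "sweep_result")
  out
}

#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_trials = sum(x$n_trials),
    mean_failure_rate = mean(x$failure_rate),
    mean_performance = mean(x$performance),
    n_memory_sets = dplyr::n_distinct(x$memory_set_kind),
    n_aux_sizes = dplyr::n_distinct(x$n_aux)
  )
}

#' @export
tidy.coupled_network <- function(x, ...) {
  blocks <- list(A = x$A, B = x$B, C = x$C, D = x$D)
  purrr::imap_dfr(blocks, function(m, nm) {
    tibble::tibble(
      block = nm,
      n_rows = nrow(m),
      n_cols = ncol(m),
      density = mean(m != 0),
      max_abs_weight = max(abs(m))
    )
  })
}

#' @export
glance.coupled_network <- function(x, ...) {
  tibble::tibble(
    n_orig = x$n_orig,
    n_aux = x$n_aux,
    k_memories = ncol(x$memories$originals),
    density_C = x$density_C,
    density_B = x$density_B,
    damage_level = x$damage_level,
    aux_fixed_points = sum(x$aux_fixed_points),
    stage = x$stage
  )
}

#' @export
tidy.memory_set <- function(x, ...) {
  ov <- pairwise_overlap_matrix(x)
  idx <- which(upper.tri(ov), arr.ind = TRUE)
  tibble::tibble(
    pattern_a = colnames(x)[idx[, 1]],
    pattern_b = colnames(x)[idx[, 2]],
    overlap = ov[idx]
  )
}

#' @export
glance.memory_set <- function(x, ...) {
  ov <- pairwise_overlap_matrix(x)
  off <- abs(ov[upper.tri(ov)])
  tibble::tibble(
    k = ncol(x),
    n_neurons = nrow(x),
    source = attr(x, "source"),
    mean_abs_overlap = if (length(off)) mean(off) else NA_real_,
    max_abs_overlap = if (length(off)) max(off) else NA_real_,
    score = if (length(off)) sum(off) else 0
  )
}
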