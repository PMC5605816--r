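#' Specify one retrieval trial condition
#'
#' A condition fixes the knobs of a retrieval experiment: cue noise,
#' damage level, feedback density, auxiliary size, which memory set is
#' encoded, whether the auxiliary network participates at all, and the
#' seed from which all per-trial randomness (lesion topology, flipped
#' pixels) is derived deterministically.
#'
#' @param noise_level fraction of cue pixels flipped, in \[0, 0.5\].
#' @param damage_level fraction of original connections removed, in
#'   \[0, 0.8\] for the reference grid (any \[0, 1\] accepted).
#' @param density_B feedback density in \[0, 0.5\] grid.
#' @param n_aux auxiliary network size (200 or 400 in the grid).
#' @param memory_set_kind `"optimal"` or `"nonoptimal"`.
#' @param auxiliary_enabled if `FALSE`, trials run the damaged original
#'   network alone (control).
#' @param seed integer condition seed.
#' @return A one-row tibble of class `trial_condition`.
#' @export
trial_condition <- function(noise_level = 0, damage_level = 0,
                            density_B = 0.25, n_aux = 200,
                            memory_set_kind = c("optimal", "nonoptimal"),
                            auxiliary_enabled = TRUE, seed = 1) {
  memory_set_kind <- match.arg(memory_set_kind)
  stopifnot_scalar_fraction(noise_level, "noise_level", 0, 0.5)
  stopifnot_scalar_fraction(damage_level, "damage_level")
  stopifnot_scalar_fraction(density_B, "density_B")
  out <- tibble::tibble(noise_level = noise_level,
                        damage_level = damage_level,
                        density_B = density_B, n_aux = as.integer(n_aux),
                        memory_set_kind = memory_set_kind,
                        auxiliary_enabled = auxiliary_enabled,
                        seed = as.integer(seed))
  class(out) <- c("trial_condition", class(out))
  out
}

#' Run one memory-retrieval trial
#'
#' Lesions the trained network at the condition's damage level (lesion
#' topology drawn from the trial seed), corrupts the chosen stored
#' memory at the condition's noise level, runs the staged recovery
#' protocol (or the damaged original network alone when
#' `auxiliary_enabled` is `FALSE`), and scores the final original-network
#' state against the cued memory.
#'
#' @param condition a [trial_condition()].
#' @param trained the undamaged trained `coupled_network` matching the
#'   condition's `n_aux` and `density_B`.
#' @param memories the original [memory_set()] encoded in `trained`.
#' @param memory_index which stored memory to cue (1..k).
#' @param config a [dynamics_config()].
#' @return A one-row tibble: `memory_index`, `retrieved` (exact match),
#'   `overlap` (final state vs cued memory), `converged`, `sweeps`.
#' @export
run_trial <- function(condition, trained, memories, memory_index,
                      config = dynamics_config()) {
  if (memory_index < 1 || memory_index > ncol(memories)) {
    stop(sprintf("memory_index %d out of range 1..%d", memory_index,
                 ncol(memories)), call. = FALSE)
  }
  trial_seed <- derive_seed(condition$seed, memory_index)
  pattern <- unclass(memories)[, memory_index]
  cue <- corrupt_cue(memory_pattern(pattern), condition$noise_level,
                     seed = derive_seed(trial_seed, 2))
  net_inj <- inject_damage(trained, condition$damage_level,
                           seed = derive_seed(trial_seed, 1))
  if (condition$auxiliary_enabled) {
    res <- recover_memory(net_inj, cue, config)
    final <- res$state
    converged <- res$converged
    sweeps <- NA_integer_
  } else {
    r <- run_to_convergence(cue, net_inj$A, config)
    final <- r$state
    converged <- r$converged
    sweeps <- r$sweeps
  }
  tibble::tibble(memory_index = as.integer(memory_index),
                 retrieved = is_retrieved(final, pattern),
                 overlap = state_overlap(final, pattern),
                 converged = converged,
                 sweeps = sweeps)
}

#' Estimate the retrieval failure rate under a condition
#'
#' Runs every stored memory through `n_repeats` independent noise and
#' lesion realizations (seeds derived deterministically from the
#' condition seed) and reports the failure rate — the fraction of
#' trials in which the original network does not converge exactly to
#' the cued memory — with its binomial standard error, plus the mean
#' retrieval performance.
#'
#' @inheritParams run_trial
#' @param n_repeats noise/damage realizations per memory.
#' @return A one-row tibble: `failure_rate`, `stderr`, `performance`,
#'   `n_trials`; the per-trial table is attached as attribute
#'   `"trials"`.
#' @export
estimate_failure_rate <- function(condition, trained, memories,
                                  n_repeats = 10,
                                  config = dynamics_config()) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  k <- ncol(memories)
  trials <- purrr::map_dfr(seq_len(n_repeats), function(rep) {
    cond_rep <- condition
    cond_rep$seed <- derive_seed(condition$seed, 1000L + rep)
    purrr::map_dfr(seq_len(k), function(mu) {
      dplyr::mutate(run_trial(cond_rep, trained, memories, mu, config),
                    repeat_index = rep)
    })
  })
  n <- nrow(trials)
  fr <- mean(!trials$retrieved)
  out <- tibble::tibble(
    failure_rate = fr,
    stderr = sqrt(fr * (1 - fr) / n),
    performance = compute_performance(trials),
    n_trials = n
  )
  attr(out, "trials") <- trials
  out
}

#' Mean retrieval performance of a set of trials
#'
#' Performance is the mean fraction of correctly recovered pixels,
#' `(1 + overlap) / 2` averaged over trials: 1 when every trial
#' retrieves exactly, 0 when every trial lands on the negated memory,
#' and 0.5 for uncorrelated final states.
#'
#' @param trial_results a data frame with an `overlap` column (as
#'   returned by [run_trial()]), or a numeric vector of overlaps.
#' @return Scalar performance in \[0, 1\].
#' @export
compute_performance <- function(trial_results) {
  ov <- if (is.data.frame(trial_results)) trial_results$overlap else trial_results
  if (length(ov) == 0) stop("no trials supplied", call. = FALSE)
  mean((1 + ov) / 2)
}
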