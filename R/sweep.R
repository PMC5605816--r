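#' Configure a parameter sweep
#'
#' Describes the full experiment grid. The reference grid crosses cue
#' noise 0-50% (5% steps), damage 0-80% (10% steps), feedback density
#' 0-50% (5% steps) and auxiliary sizes 200 and 400, with interface
#' density fixed at 5%, for 20 memories over 1000 neurons; the defaults
#' here are a coarsened version so that example sweeps finish quickly.
#' Calibration (C, auxiliary patterns, D, B) happens once per memory
#' set and auxiliary size, before any damage; lesions are redrawn per
#' trial.
#'
#' @param noise_grid cue noise levels.
#' @param damage_grid damage levels.
#' @param density_B_grid feedback densities.
#' @param n_aux_grid auxiliary sizes.
#' @param memory_set_kinds subset of `c("optimal", "nonoptimal")`.
#' @param n_orig original network size.
#' @param k_memories stored memories per set.
#' @param n_candidates candidate pool size from which the optimal
#'   subset is chosen.
#' @param n_shared memories shared between optimal and nonoptimal sets.
#' @param density_C interface density.
#' @param n_repeats noise/lesion realizations per memory per cell.
#' @param master_seed single seed from which every other seed derives.
#' @param max_sweeps dynamics iteration cap.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(noise_grid = seq(0, 0.5, by = 0.1),
                         damage_grid = seq(0, 0.8, by = 0.2),
                         density_B_grid = seq(0, 0.5, by = 0.1),
                         n_aux_grid = c(200L, 400L),
                         memory_set_kinds = c("optimal", "nonoptimal"),
                         n_orig = 1000, k_memories = 20,
                         n_candidates = 30, n_shared = 15,
                         density_C = 0.05, n_repeats = 10,
                         master_seed = 1, max_sweeps = 50) {
  grids <- list(noise_grid = noise_grid, damage_grid = damage_grid,
                density_B_grid = density_B_grid)
  for (nm in names(grids)) {
    bad <- grids[[nm]] < 0 | grids[[nm]] > 1
    if (any(bad)) {
      stop(sprintf("%s contains values outside [0, 1]: %s", nm,
                   paste(grids[[nm]][bad], collapse = ", ")), call. = FALSE)
    }
  }
  if (any(noise_grid > 0.5)) {
    stop("noise_grid values must not exceed 0.5", call. = FALSE)
  }
  structure(list(noise_grid = noise_grid, damage_grid = damage_grid,
                 density_B_grid = density_B_grid,
                 n_aux_grid = as.integer(n_aux_grid),
                 memory_set_kinds = match.arg(memory_set_kinds,
                                              c("optimal", "nonoptimal"),
                                              several.ok = TRUE),
                 n_orig = n_orig, k_memories = k_memories,
                 n_candidates = n_candidates, n_shared = n_shared,
                 density_C = density_C, n_repeats = n_repeats,
                 master_seed = master_seed, max_sweeps = max_sweeps),
            class = "sweep_config")
}

#' Build the optimal and nonoptimal memory sets for a sweep
#'
#' Generates the synthetic candidate pool (default 30 patterns: 22
#' independent plus a correlated glyph-like cluster of 8, via
#' [generate_candidate_pool()]), selects the most orthogonal `k` as the
#' optimal set, and derives the nonoptimal set sharing `n_shared`
#' members — whose random replacements typically reintroduce correlated
#' candidates, reproducing the optimal/nonoptimal performance contrast.
#'
#' @param config a [sweep_config()].
#' @return Named list with `candidates`, `optimal`, `nonoptimal`.
#' @export
build_sweep_memory_sets <- function(config) {
  n_cor <- max(0L, round(config$n_candidates * 8 / 30))
  candidates <- generate_candidate_pool(
    n_independent = config$n_candidates - n_cor,
    n_correlated = n_cor,
    n_neurons = config$n_orig,
    seed = derive_seed(config$master_seed, 11)
  )
  optimal <- select_optimal_subset(candidates, k = config$k_memories)
  nonoptimal <- make_nonoptimal_set(optimal, candidates,
                                    n_shared = config$n_shared,
                                    seed = derive_seed(config$master_seed, 12))
  list(candidates = candidates, optimal = optimal, nonoptimal = nonoptimal)
}

#' Run a failure-rate / performance parameter sweep
#'
#' Iterates the cross-product of the configured grids. For each memory
#' set and auxiliary size the coupled network is calibrated once
#' (training seed fixed by the master seed); the feedback block is
#' rebuilt per feedback density; lesions and cue noise are redrawn per
#' trial from seeds derived deterministically from the master seed, so
#' an identical configuration reproduces the sweep exactly.
#'
#' @param config a [sweep_config()].
#' @param progress print per-cell progress to stderr.
#' @return A tibble of class `sweep_result`: one row per grid cell with
#'   the condition columns, `failure_rate`, `performance`, `stderr` and
#'   `n_trials`; the configuration is attached as attribute `"config"`.
#' @export
run_sweep <- function(config = sweep_config(), progress = FALSE) {
  sets <- build_sweep_memory_sets(config)
  dyn <- dynamics_config(max_sweeps = config$max_sweeps)
  grid <- tidyr::expand_grid(
    memory_set_kind = config$memory_set_kinds,
    n_aux = config$n_aux_grid,
    density_B = config$density_B_grid,
    damage_level = config$damage_grid,
    noise_level = config$noise_grid
  )
  nets <- list()
  rows <- purrr::pmap_dfr(grid, function(memory_set_kind, n_aux, density_B,
                                         damage_level, noise_level) {
    memories <- sets[[memory_set_kind]]
    net_key <- sprintf("%s_%d_%g", memory_set_kind, n_aux, density_B)
    if (is.null(nets[[net_key]])) {
      nets[[net_key]] <<- train_augmented_network(
        memories, n_aux = n_aux,
        density_C = config$density_C, density_B = density_B,
        seed = derive_seed(config$master_seed, 21,
                           match(memory_set_kind, c("optimal", "nonoptimal")),
                           n_aux)
      )
    }
    cond <- trial_condition(
      noise_level = noise_level, damage_level = damage_level,
      density_B = density_B, n_aux = n_aux,
      memory_set_kind = memory_set_kind,
      seed = derive_seed(config$master_seed, 31,
                         round(1000 * noise_level),
                         round(1000 * damage_level),
                         round(1000 * density_B), n_aux,
                         match(memory_set_kind, c("optimal", "nonoptimal")))
    )
    est <- estimate_failure_rate(cond, nets[[net_key]], memories,
                                 n_repeats = config$n_repeats, config = dyn)
    if (progress) {
      message(sprintf(
        "cell %s n_aux=%d B=%.2f damage=%.2f noise=%.2f: failure %.3f",
        memory_set_kind, n_aux, density_B, damage_level, noise_level,
        est$failure_rate))
    }
    tibble::tibble(memory_set_kind = memory_set_kind,
                   n_aux = as.integer(n_aux),
                   density_B = density_B, damage_level = damage_level,
                   noise_level = noise_level,
                   failure_rate = est$failure_rate,
                   performance = est$performance,
                   stderr = est$stderr, n_trials = est$n_trials)
  })
  attr(rows, "config") <- config
  class(rows) <- c("sweep_result", class(rows))
  rows
}

#' Write sweep outputs to a directory
#'
#' Writes the tidy per-cell CSV (`sweep.csv`, one row per grid cell)
#' and, optionally, per-density performance heatmaps
#' (`performance_<set>_<n_aux>_B<density>.png`) of performance against
#' damage and noise. Identical sweep results produce byte-identical
#' CSV files.
#'
#' @param result a `sweep_result` tibble.
#' @param out_dir output directory, created if missing.
#' @param plots also write heatmap PNGs.
#' @return Invisibly, the paths written.
#' @export
write_sweep_outputs <- function(result, out_dir, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "sweep.csv")
  readr::write_csv(result, csv)
  paths <- csv
  if (plots && nrow(result) > 0) {
    combos <- dplyr::distinct(result, .data$memory_set_kind, .data$n_aux,
                              .data$density_B)
    for (i in seq_len(nrow(combos))) {
      sub <- dplyr::semi_join(result, combos[i, ],
                              by = c("memory_set_kind", "n_aux", "density_B"))
      p <- plot_performance_surface(sub)
      f <- file.path(out_dir, sprintf("performance_%s_%d_B%02.0f.png",
                                      combos$memory_set_kind[i],
                                      combos$n_aux[i],
                                      100 * combos$density_B[i]))
      ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' @rdname write_sweep_outputs
#' @param path a `sweep.csv` written by [write_sweep_outputs()].
#' @export
read_sweep_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    memory_set_kind = readr::col_character(),
    n_aux = readr::col_integer(),
    density_B = readr::col_double(),
    damage_level = readr::col_double(),
    noise_level = readr::col_double(),
    failure_rate = readr::col_double(),
    performance = readr::col_double(),
    stderr = readr::col_double(),
    n_trials = readr::col_integer()
  ))
  class(out) <- c("sweep_result", class(out))
  out
}
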