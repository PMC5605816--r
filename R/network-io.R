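#' Save and load a trained coupled network
#'
#' Serializes every block (`A`, `B`, `C`, `D`), the augmented memory
#' set, densities, seeds and damage state to a single JSON container.
#' The loader validates the block-shape invariants (`A`: n_orig^2,
#' `B`: n_orig x n_aux, `C`: n_aux x n_orig, `D`: n_aux^2) before
#' reconstructing the object.
#'
#' @param net a `coupled_network`.
#' @param path file path (`.json`; pass a `gzfile()`-compatible path
#'   ending in `.gz` to compress).
#' @return `save_network()` returns `path` invisibly; `load_network()`
#'   the reconstructed `coupled_network`.
#' @export
save_network <- function(net, path) {
  payload <- list(
    format = "auxmem_network", version = 1L,
    n_orig = net$n_orig, n_aux = net$n_aux,
    density_C = net$density_C, density_B = net$density_B,
    c_weights = net$c_weights, b_weights = net$b_weights,
    seed = net$seed, stage = net$stage,
    damage_level = net$damage_level,
    damage_seed = net$damage_seed,
    aux_fixed_points = net$aux_fixed_points,
    labels = colnames(net$memories$originals),
    source = attr(net$memories$originals, "source"),
    A = net$A, B = net$B, C = net$C, D = net$D,
    originals = unclass(net$memories$originals),
    auxiliaries = unclass(net$memories$auxiliaries)
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  x <- jsonlite::fromJSON(paste(readLines(con), collapse = ""))
  if (!identical(x$format, "auxmem_network")) {
    stop("not an auxmem network container: ", path, call. = FALSE)
  }
  n_o <- x$n_orig
  n_a <- x$n_aux
  shapes <- list(A = c(n_o, n_o), B = c(n_o, n_a),
                 C = c(n_a, n_o), D = c(n_a, n_a))
  for (blk in names(shapes)) {
    got <- dim(x[[blk]])
    if (!identical(as.integer(got), as.integer(shapes[[blk]]))) {
      stop(sprintf("block %s has shape %s, expected %s", blk,
                   paste(got, collapse = "x"),
                   paste(shapes[[blk]], collapse = "x")), call. = FALSE)
    }
  }
  orig <- x$originals
  colnames(orig) <- x$labels
  aux <- x$auxiliaries
  colnames(aux) <- x$labels
  structure(list(A = x$A, B = x$B, C = x$C, D = x$D,
                 memories = list(originals = memory_set(orig, source = x$source),
                                 auxiliaries = memory_set(aux, source = x$source)),
                 n_orig = n_o, n_aux = n_a,
                 density_C = x$density_C, density_B = x$density_B,
                 c_weights = x$c_weights, b_weights = x$b_weights,
                 seed = x$seed, stage = x$stage,
                 damage_level = x$damage_level,
                 damage_seed = x$damage_seed,
                 aux_fixed_points = x$aux_fixed_points),
            class = "coupled_network")
}
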