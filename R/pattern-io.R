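#' Read and write memory patterns as plain text
#'
#' The pattern file format stores one pattern per record: a header line
#' `>label height width` followed by `height` lines of `width`
#' characters in `{0, 1}` (`0` = -1, `1` = +1), flattened row-major.
#' Reading back a written file reproduces the set bit-exactly.
#'
#' @param set a [memory_set()].
#' @param path file path.
#' @param height,width bitmap shape used to lay the pattern out; must
#'   satisfy `height * width == n_neurons(set)`.
#' @return `write_patterns()` returns `path` invisibly;
#'   `read_patterns()` returns a [memory_set()].
#' @export
write_patterns <- function(set, path, height = NULL, width = NULL) {
  n <- nrow(set)
  if (is.null(height) || is.null(width)) {
    height <- if (n == 1000L) 40L else n
    width <- if (n == 1000L) 25L else 1L
  }
  if (height * width != n) {
    stop(sprintf("height * width = %d does not match pattern length %d",
                 height * width, n), call. = FALSE)
  }
  lines <- character(0)
  for (k in seq_len(ncol(set))) {
    bits <- ifelse(unclass(set)[, k] == 1L, "1", "0")
    rows <- vapply(seq_len(height), function(r) {
      paste(bits[((r - 1) * width + 1):(r * width)], collapse = "")
    }, character(1))
    lines <- c(lines, sprintf(">%s %d %d", colnames(set)[k], height, width), rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_patterns
#' @param source tag attached to the set read back.
#' @export
read_patterns <- function(path, source = "candidate_pool") {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no pattern records found in ", path, call. = FALSE)
  pats <- lapply(seq_along(hdr), function(i) {
    parts <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    label <- parts[1]
    height <- as.integer(parts[2])
    width <- as.integer(parts[3])
    body <- lines[(hdr[i] + 1):(hdr[i] + height)]
    bits <- unlist(strsplit(body, ""))
    if (length(bits) != height * width || !all(bits %in% c("0", "1"))) {
      stop(sprintf("malformed record '%s'", label), call. = FALSE)
    }
    memory_pattern(ifelse(bits == "1", 1L, -1L), label = label)
  })
  memory_set(pats, source = source)
}

#' Export one pattern as a PBM (P1) image
#'
#' Plain-text portable bitmap; ink (-1) pixels are written as 1 (black)
#' so the glyph renders dark on white, matching the bitmap convention.
#'
#' @param pattern a [memory_pattern()] or ±1 vector.
#' @param path output file path.
#' @param height,width bitmap shape (`height * width` must equal the
#'   pattern length).
#' @export
write_pbm <- function(pattern, path, height = 40, width = 25) {
  if (height * width != length(pattern)) {
    stop("height * width must equal the pattern length", call. = FALSE)
  }
  px <- ifelse(as.integer(pattern) == -1L, "1", "0")
  rows <- vapply(seq_len(height), function(r) {
    paste(px[((r - 1) * width + 1):(r * width)], collapse = " ")
  }, character(1))
  writeLines(c("P1", sprintf("%d %d", width, height), rows), path)
  invisible(path)
}
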