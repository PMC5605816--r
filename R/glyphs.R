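# Bitmap-font glyph rendering.
#
# Each glyph is defined on a classic 5x7 dot-matrix grid (rows top to
# bottom, '#' = ink) and scaled by nearest-neighbour into the requested
# tile (default 40 x 25) with a margin, then thresholded to ±1 pixels.
# The renderer needs no system fonts, so rendered sets are identical on
# every platform.

# 5-column rows per glyph; 7 rows each.
.glyph_font <- list(
  "0" = c("01110","10001","10011","10101","11001","10001","01110"),
  "1" = c("00100","01100","00100","00100","00100","00100","01110"),
  "2" = c("01110","10001","00001","00010","00100","01000","11111"),
  "3" = c("11111","00010","00100","00010","00001","10001","01110"),
  "4" = c("00010","00110","01010","10010","11111","00010","00010"),
  "5" = c("11111","10000","11110","00001","00001","10001","01110"),
  "6" = c("00110","01000","10000","11110","10001","10001","01110"),
  "7" = c("11111","00001","00010","00100","01000","01000","01000"),
  "8" = c("01110","10001","10001","01110","10001","10001","01110"),
  "9" = c("01110","10001","10001","01111","00001","00010","01100"),
  "A" = c("01110","10001","10001","11111","10001","10001","10001"),
  "B" = c("11110","10001","10001","11110","10001","10001","11110"),
  "C" = c("01110","10001","10000","10000","10000","10001","01110"),
  "D" = c("11100","10010","10001","10001","10001","10010","11100"),
  "E" = c("11111","10000","10000","11110","10000","10000","11111"),
  "F" = c("11111","10000","10000","11110","10000","10000","10000"),
  "G" = c("01110","10001","10000","10111","10001","10001","01111"),
  "H" = c("10001","10001","10001","11111","10001","10001","10001"),
  "I" = c("01110","00100","00100","00100","00100","00100","01110"),
  "J" = c("00111","00010","00010","00010","00010","10010","01100"),
  "K" = c("10001","10010","10100","11000","10100","10010","10001"),
  "L" = c("10000","10000","10000","10000","10000","10000","11111"),
  "M" = c("10001","11011","10101","10101","10001","10001","10001"),
  "N" = c("10001","10001","11001","10101","10011","10001","10001"),
  "O" = c("01110","10001","10001","10001","10001","10001","01110"),
  "P" = c("11110","10001","10001","11110","10000","10000","10000"),
  "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
  "R" = c("11110","10001","10001","11110","10100","10010","10001"),
  "S" = c("01111","10000","10000","01110","00001","00001","11110"),
  "T" = c("11111","00100","00100","00100","00100","00100","00100"),
  "U" = c("10001","10001","10001","10001","10001","10001","01110"),
  "V" = c("10001","10001","10001","10001","10001","01010","00100"),
  "W" = c("10001","10001","10001","10101","10101","10101","01010"),
  "X" = c("10001","10001","01010","00100","01010","10001","10001"),
  "Y" = c("10001","10001","10001","01010","00100","00100","00100"),
  "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
  "+" = c("00000","00100","00100","11111","00100","00100","00000"),
  "*" = c("00000","10101","01110","11111","01110","10101","00000"),
  "#" = c("01010","01010","11111","01010","11111","01010","01010"),
  "?" = c("01110","10001","00001","00010","00100","00000","00100")
)

# Rasterize one glyph to a height x width luminance image in [0, 1]
# (0 = ink). Nearest-neighbour scaling of the 7x5 grid into the tile
# interior, one-cell margin all round; background luminance 1.
glyph_luminance <- function(glyph, height, width) {
  rows <- .glyph_font[[glyph]]
  if (is.null(rows)) {
    stop(sprintf("glyph '%s' is not in the built-in bitmap font", glyph),
         call. = FALSE)
  }
  bits <- do.call(rbind, lapply(rows, function(r) {
    as.integer(strsplit(r, "")[[1]])
  }))
  img <- matrix(1, height, width)
  # map tile interior back onto the 7x5 glyph grid
  r0 <- max(1L, round(height * 0.08)); r1 <- height - r0 + 1L
  c0 <- max(1L, round(width * 0.08));  c1 <- width - c0 + 1L
  for (i in r0:r1) {
    gi <- ceiling((i - r0 + 1) / (r1 - r0 + 1) * 7)
    for (j in c0:c1) {
      gj <- ceiling((j - c0 + 1) / (c1 - c0 + 1) * 5)
      if (bits[gi, gj] == 1L) img[i, j] <- 0
    }
  }
  img
}

#' Render glyphs to binary memory patterns
#'
#' Rasterizes each glyph from a built-in 5x7 dot-matrix bitmap font into
#' a `height` x `width` tile and thresholds pixel luminance: luminance
#' below `threshold` maps to -1 (black/ink), otherwise +1 (white). The
#' tile is flattened row-major (row 1 = top of the glyph) into a pattern
#' of `height * width` neurons. A glyph rendering to a constant tile is
#' flagged degenerate with a warning.
#'
#' @param glyphs character vector of single glyphs; see names of
#'   supported glyphs via `auxmem_font_glyphs()`.
#' @param height,width tile size in pixels (default 40 x 25, i.e. 1000
#'   neurons).
#' @param threshold luminance cutoff in (0, 1); ink pixels have
#'   luminance 0, background 1.
#' @return A [memory_set()] labelled by the glyphs,
#'   tagged `"candidate_pool"`.
#' @examples
#' gs <- render_glyph_patterns(c("A", "B", "C"))
#' n_neurons(gs)
#' @export
render_glyph_patterns <- function(glyphs, height = 40, width = 25,
                                  threshold = 0.5) {
  glyphs <- as.character(glyphs)
  if (anyDuplicated(glyphs)) stop("glyphs must be unique", call. = FALSE)
  M <- vapply(glyphs, function(g) {
    img <- glyph_luminance(g, height, width)
    pat <- ifelse(t(img) < threshold, -1L, 1L) # t(): row-major flatten
    as.integer(pat)
  }, integer(height * width))
  degenerate <- apply(M, 2, function(x) length(unique(x)) == 1L)
  if (any(degenerate)) {
    warning(sprintf("degenerate (constant) glyph pattern(s): %s",
                    paste(glyphs[degenerate], collapse = ", ")),
            call. = FALSE)
  }
  memory_set(M, source = "candidate_pool")
}

#' Glyphs available in the built-in bitmap font
#' @return Character vector of renderable glyphs.
#' @export
auxmem_font_glyphs <- function() names(.glyph_font)
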