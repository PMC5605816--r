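#' Read and write weight matrices
#'
#' Dense CSV (one row per neuron, no header) and a gzip-compressed
#' binary container with a version header. Both round-trip integer
#' Hebbian weights bit-exactly.
#'
#' @param weights square numeric weight matrix.
#' @param path file path.
#' @return Writers return `path` invisibly; readers return the matrix.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.table(weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                     colClasses = "numeric")))
}

# container magic + format version
.weights_bin_magic <- "AUXMEMW"
.weights_bin_version <- 1L

#' @rdname write_weights_csv
#' @export
write_weights_bin <- function(weights, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeChar(.weights_bin_magic, con, eos = NULL)
  writeBin(.weights_bin_version, con, size = 4L, endian = "little")
  writeBin(c(nrow(weights), ncol(weights)), con, size = 4L, endian = "little")
  writeBin(as.double(weights), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_bin <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(.weights_bin_magic), useBytes = TRUE)
  if (!identical(magic, .weights_bin_magic)) {
    stop("not an auxmem weight container: ", path, call. = FALSE)
  }
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != .weights_bin_version) {
    stop("unsupported weight container version ", version, call. = FALSE)
  }
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  vals <- readBin(con, "double", dims[1] * dims[2], size = 8L,
                  endian = "little")
  matrix(vals, dims[1], dims[2])
}
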