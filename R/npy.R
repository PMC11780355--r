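# Minimal NumPy .npy (format version 1.0) reader/writer for the 1-D
# little-endian arrays found in Kilosort/Phy exports (spike_times.npy,
# spike_clusters.npy). Only what those files need: int32/uint32/int64/float64
# vectors.

npy_dtypes <- list(
  "<i4" = list(what = integer(), size = 4L, signed = TRUE),
  "<u4" = list(what = integer(), size = 4L, signed = FALSE),
  "<i8" = list(what = numeric(), size = 8L, signed = TRUE),  # via double
  "<f8" = list(what = numeric(), size = 8L, signed = TRUE)
)

#' Read and write 1-D NumPy arrays
#'
#' Minimal support for the `.npy` format (version 1.0, little-endian,
#' C-order, one-dimensional) used by Kilosort/Phy spike exports. 64-bit
#' integers are read into doubles (spike sample indices are far below 2^53,
#' so the conversion is exact).
#'
#' @param path File path.
#' @param x Numeric vector to write.
#' @param dtype One of `"<i8"` (default for integers), `"<f8"`, `"<i4"`,
#'   `"<u4"`.
#' @return `read_npy`: numeric vector; `write_npy`: `path`, invisibly.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    rlang::abort(sprintf("%s is not an npy file (bad magic)", path))
  }
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  if (grepl("'fortran_order':\\s*True", header)) {
    rlang::abort("fortran-order npy arrays are not supported")
  }
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.numeric(strsplit(gsub("[[:space:]]", "", shape), ",")[[1]])
  n <- prod(dims[!is.na(dims)])
  dt <- npy_dtypes[[descr]]
  if (is.null(dt)) rlang::abort(sprintf("unsupported npy dtype '%s'", descr))
  if (dt$size == 8 && descr == "<i8") {
    raw <- readBin(con, "raw", n * 8)
    m <- matrix(as.numeric(raw), nrow = 8)
    # little-endian int64 -> double; values in spike files are non-negative
    # and < 2^53 so this is exact
    out <- as.numeric(2^(8 * (0:7)) %*% m)
    hi <- m[8, ]
    if (any(hi > 127)) rlang::abort("negative int64 values not supported")
    out
  } else {
    out <- readBin(con, if (is.integer(dt$what)) "integer" else "double", n,
                   size = dt$size, endian = "little")
    # uint32 is read through the signed type; ids above 2^31 do not occur in
    # spike exports
    if (descr == "<u4" && any(out < 0)) {
      rlang::abort("uint32 values above 2^31 are not supported")
    }
    out
  }
}

#' @rdname read_npy
#' @export
write_npy <- function(x, path, dtype = if (is.double(x) && !all(x == round(x))) "<f8" else "<i8") {
  if (is.null(npy_dtypes[[dtype]])) {
    rlang::abort(sprintf("unsupported npy dtype '%s'", dtype))
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%d,), }",
                    dtype, length(x))
  # pad so that magic(6) + version(2) + len(2) + header is a multiple of 64
  total <- 10 + nchar(header) + 1
  pad <- (64 - total %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  if (dtype == "<i8") {
    stopifnot(all(x >= 0), all(x < 2^53))
    v <- as.numeric(x)
    bytes <- raw(8 * length(v))
    for (b in 0:7) {
      bytes[seq_along(v) * 8 - 7 + b] <- as.raw(floor(v / 2^(8 * b)) %% 256)
    }
    writeBin(bytes, con)
  } else if (dtype == "<f8") {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = 4, endian = "little")
  }
  invisible(path)
}
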