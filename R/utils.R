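# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Pack a vector of unsigned 16-bit values (stored as R integers in
# [0, 65535]) into little-endian raw bytes. writeBin() truncates to the low
# 16 bits only for values that fit in a signed short, so values >= 2^15 are
# mapped to their two's-complement representation first.
u16_pack <- function(x) {
  x <- as.integer(x)
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2L, endian = "little")
}

u16_unpack <- function(bytes, n = length(bytes) / 2L) {
  readBin(bytes, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
}

u32_pack <- function(x) {
  # lengths can exceed .Machine$integer.max in principle; doubles are exact
  # far beyond the sizes handled here
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(u16_pack(lo), u16_pack(hi))
}

u32_unpack <- function(bytes, n = length(bytes) / 4L) {
  v <- u16_unpack(bytes, n = 2L * n)
  v[seq(1L, 2L * n, by = 2L)] + 65536 * v[seq(2L, 2L * n, by = 2L)]
}

# Read exactly n raw bytes from a connection, erroring on short reads.
read_exact <- function(con, n, what = "data") {
  if (n == 0) return(raw(0))
  out <- readBin(con, "raw", n = n)
  if (length(out) < n) {
    stop(sprintf("truncated file: expected %d bytes of %s, got %d",
                 n, what, length(out)), call. = FALSE)
  }
  out
}
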