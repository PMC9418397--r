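# Minimal 8-bit grayscale PNG writer.
#
# The installed stack has no PNG package, and the export is a convenience
# interface only, so the format is written directly: IHDR/tEXt/IDAT/IEND
# chunks, the IDAT zlib stream from base R's memCompress (whose "gzip" type
# is in fact zlib-wrapped deflate), and a table-driven CRC-32. 32-bit
# bitwise ops are done on doubles split into 16-bit halves, since R
# integers cannot hold unsigned 32-bit values.

#' @noRd
xor32 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

#' @noRd
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (i in 1:8) {
          c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

#' @noRd
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- xor32(crc %/% 256, tab[bitwXor(crc %% 256, b[i]) + 1])
  }
  xor32(crc, 4294967295)
}

#' @noRd
u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

#' @noRd
png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

# base R's memCompress(type = "gzip") emits a zlib stream (CMF/FLG header +
# deflate + Adler-32), which is exactly what a PNG IDAT chunk needs
#' @noRd
zlib_compress <- function(raw_bytes) {
  memCompress(raw_bytes, type = "gzip")
}

#' Write an 8-bit grayscale PNG
#'
#' @param gray integer matrix of gray levels in 0..255 (rows = image rows).
#' @param path output file path.
#' @param text optional named character vector written as tEXt chunks
#'   (e.g. the temperature window used for scaling).
#' @return `path`, invisibly.
#' @keywords internal
write_png_gray <- function(gray, path, text = NULL) {
  stopifnot(is.matrix(gray), all(gray >= 0), all(gray <= 255))
  H <- nrow(gray); W <- ncol(gray)
  ihdr <- c(u32be(W), u32be(H), as.raw(c(8, 0, 0, 0, 0)))
  # scanlines: filter byte 0 then the row's samples
  m <- rbind(rep(0L, H), t(gray))  # columns are scanlines: filter + W samples
  scan <- as.raw(as.vector(m))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr))
  for (key in names(text)) {
    out <- c(out, png_chunk("tEXt", c(charToRaw(key), as.raw(0),
                                      charToRaw(text[[key]]))))
  }
  out <- c(out, png_chunk("IDAT", zlib_compress(scan)), png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
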