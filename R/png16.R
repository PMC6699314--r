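# Minimal 16-bit grayscale PNG encoder. The png package reads 16-bit PNGs
# (values come back as k/65535) but only writes 8-bit files, so the 16-bit
# write path is implemented here: one IHDR/IDAT/IEND stream, filter type 0
# on every scanline, zlib via memCompress. Round trips through png::readPNG
# are bit-exact and covered by tests.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    c <- bitwXor(tab[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

int_to_be4 <- function(x) {
  # unsigned 32-bit big-endian bytes from a (possibly negative) R integer
  u <- if (x < 0) x + 4294967296 else as.numeric(x)
  as.raw(c(u %/% 16777216, (u %/% 65536) %% 256, (u %/% 256) %% 256, u %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_be4(length(data)), body, int_to_be4(crc32(body)))
}

write_png16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  v <- round(pixels)
  if (min(v) < 0 || max(v) > 65535) stop("16-bit pixel values out of range")
  h <- nrow(v); w <- ncol(v)
  # scanlines are rows; each preceded by filter byte 0; samples big-endian
  vt <- t(v) # row-major order
  hi <- as.raw(vt %/% 256L)
  lo <- as.raw(vt %% 256L)
  samples <- as.raw(rbind(hi, lo)) # interleave hi/lo per sample
  dim(samples) <- NULL
  scan <- matrix(samples, nrow = 2L * w)
  raw_stream <- as.raw(rbind(matrix(as.raw(0L), 1L, h), scan))
  dim(raw_stream) <- NULL
  ihdr <- c(int_to_be4(w), int_to_be4(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(
    as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", memCompress(raw_stream, type = "gzip")),
    png_chunk("IEND", raw())
  )
  writeBin(out, path)
  invisible(path)
}
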