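# Minimal 8-bit indexed (color type 3) PNG writer and reader for label
# masks, where the palette index IS the class id.  No installed package
# writes palette PNGs, so the container is assembled here: IHDR/PLTE/IDAT
# chunks with CRC-32, and a zlib stream obtained by rewrapping the deflate
# payload of memCompress().

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
           else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

int_to_be4 <- function(x) {
  # x: nonnegative value (double ok) or signed 32-bit pattern
  if (x < 0) x <- x + 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  c(int_to_be4(length(data)), payload, int_to_be4(crc32(payload)))
}

adler32 <- function(bytes) {
  b <- as.double(as.integer(bytes))
  n <- length(b)
  s1 <- (1 + sum(b)) %% 65521
  s2 <- (n + sum(rev(seq_len(n)) * b)) %% 65521
  s2 * 65536 + s1
}

# PNG IDAT wants a zlib stream (RFC 1950): 0x78 0x9C header + deflate +
# Adler-32.  memCompress(type = "gzip") emits exactly that format; the
# header and checksum are verified rather than trusted.
zlib_compress <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")
  stopifnot(z[1] == as.raw(0x78),
            identical(z[(length(z) - 3L):length(z)],
                      int_to_be4(adler32(bytes))))
  z
}

#' Write an 8-bit indexed PNG
#'
#' @param indices integer matrix (values 0..255); each value is stored as
#'   a palette index, so reading the file back recovers the matrix exactly.
#' @param palette_rgb `n x 3` matrix of RGB 0..255 palette entries; entry
#'   `i + 1` renders index `i`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indexed_png <- function(indices, palette_rgb, path) {
  stopifnot(is.matrix(indices), min(indices) >= 0, max(indices) <= 255)
  palette_rgb <- as.matrix(palette_rgb)
  stopifnot(ncol(palette_rgb) == 3L, nrow(palette_rgb) >= max(indices) + 1L,
            min(palette_rgb) >= 0, max(palette_rgb) <= 255)
  h <- nrow(indices); w <- ncol(indices)
  ihdr <- c(int_to_be4(w), int_to_be4(h),
            as.raw(c(8L, 3L, 0L, 0L, 0L)))  # depth 8, palette, no interlace
  plte <- as.raw(as.integer(t(palette_rgb)))
  # scanlines: filter byte 0 then the row's indices
  raw_rows <- rbind(0L, t(indices))
  idat <- zlib_compress(as.raw(as.integer(raw_rows)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("PLTE", plte), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

# scan the chunk list for the raw PLTE entries
read_png_palette <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 9L  # past signature
  while (pos + 8L <= length(bytes)) {
    len <- sum(as.integer(bytes[pos:(pos + 3L)]) * c(16777216, 65536, 256, 1))
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    if (type == "PLTE") {
      ent <- as.integer(bytes[(pos + 8L):(pos + 7L + len)])
      return(matrix(ent, ncol = 3L, byrow = TRUE))
    }
    pos <- pos + 12L + len
  }
  stop("no PLTE chunk: not an indexed PNG: ", path, call. = FALSE)
}

#' Read an 8-bit indexed PNG
#'
#' Recovers the palette indices exactly (palette entries must be distinct
#' colors, as written by [write_indexed_png()]).
#'
#' @param path path to an indexed PNG.
#' @return list with `indices` (integer matrix) and `palette` (`n x 3`
#'   RGB 0..255 matrix).
#' @export
read_indexed_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pal <- read_png_palette(path)
  if (anyDuplicated(pal))
    stop("palette has duplicate colors; indices are not recoverable",
         call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3L)
    stop("expected a color-expanded indexed PNG", call. = FALSE)
  rgb255 <- floor(arr[, , 1:3, drop = FALSE] * 255 + 0.5)
  key <- rgb255[, , 1] * 65536 + rgb255[, , 2] * 256 + rgb255[, , 3]
  palkey <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
  idx <- match(as.vector(key), palkey) - 1L
  if (anyNA(idx))
    stop("pixel color not present in palette: corrupt file?", call. = FALSE)
  list(indices = matrix(idx, nrow = nrow(key), ncol = ncol(key)),
       palette = pal)
}
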