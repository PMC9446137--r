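#' Construct a raster image
#'
#' A `raster_image` is an H x W x 3 numeric array of red, green and blue
#' intensities in `[0, 1]`.  All pixel processing in the package happens in
#' this continuous domain; quantization to 8 bits occurs only at file I/O.
#'
#' @param data numeric array `H x W x 3` with values in `[0, 1]`, or an
#'   `H x W` matrix (replicated to three identical channels).
#' @return a `raster_image`.
#' @export
raster_image <- function(data) {
  if (is.matrix(data)) data <- array(rep(data, 3), dim = c(dim(data), 3L))
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop("`data` must be an H x W x 3 array or an H x W matrix", call. = FALSE)
  if (dim(data)[1] < 1L || dim(data)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(data) || min(data) < 0 || max(data) > 1)
    stop("channel values must lie in [0, 1]", call. = FALSE)
  structure(data, class = c("raster_image", "array"))
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %d x %d, RGB in [0,1]>\n", d[1], d[2]))
  invisible(x)
}

#' @rdname raster_image
#' @param x object to test.
#' @export
is_raster_image <- function(x) inherits(x, "raster_image")

assert_image <- function(img) {
  if (!is_raster_image(img)) stop("expected a `raster_image`", call. = FALSE)
  invisible(img)
}

#' Image dimensions
#' @param img a `raster_image`.
#' @return integer vector `c(height, width)`.
#' @export
image_dim <- function(img) {
  assert_image(img)
  dim(img)[1:2]
}

#' Load a PNG or JPEG file as a raster image
#'
#' Values are scaled to `[0, 1]`; an alpha channel is dropped and grayscale
#' content is replicated to three channels.
#'
#' @param path path to a PNG or JPEG file.
#' @return a `raster_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 3L)
  arr <- if (length(magic) >= 3L && identical(magic[2:3], as.raw(c(0x50, 0x4e))))
    png::readPNG(path)
  else if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8))))
    jpeg::readJPEG(path)
  else
    stop("not a decodable PNG or JPEG: ", path, call. = FALSE)
  if (is.matrix(arr)) arr <- array(rep(arr, 3), dim = c(dim(arr), 3L))
  if (dim(arr)[3] == 2L) arr <- array(rep(arr[, , 1], 3), dim = c(dim(arr)[1:2], 3L))
  if (dim(arr)[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  raster_image(arr)
}

#' Save a raster image as an 8-bit PNG
#'
#' Channel value `v` is written as `round(v * 255)` (round half up), so a
#' save/load round trip is exact for images already on the 8-bit grid.
#'
#' @param img a `raster_image`.
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  assert_image(img)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  q <- floor(unclass(img) * 255 + 0.5) / 255
  png::writePNG(q, path)
  invisible(path)
}

#' Convert a raster image to CIELAB
#'
#' Uses the exact piecewise sRGB transfer function and the D65 white point
#' (Xn = 0.95047, Yn = 1, Zn = 1.08883).  L is in `[0, 100]`.
#'
#' @param img a `raster_image`.
#' @return an `H x W x 3` array of (L, a, b), class `lab_image`.
#' @export
to_lab <- function(img) {
  assert_image(img)
  d <- dim(img)
  v <- unclass(img)
  # linearize sRGB
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  R <- lin[, , 1]; G <- lin[, , 2]; B <- lin[, , 3]
  X <- 0.4124564 * R + 0.3575761 * G + 0.1804375 * B
  Y <- 0.2126729 * R + 0.7151522 * G + 0.0721750 * B
  Z <- 0.0193339 * R + 0.1191920 * G + 0.9503041 * B
  f <- function(t) {
    d3 <- (6 / 29)^3
    ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  }
  fx <- f(X / 0.95047); fy <- f(Y); fz <- f(Z / 1.08883)
  out <- array(0, dim = d)
  out[, , 1] <- 116 * fy - 16
  out[, , 2] <- 500 * (fx - fy)
  out[, , 3] <- 200 * (fy - fz)
  structure(out, class = c("lab_image", "array"))
}

#' Gamma-correct a raster image
#'
#' Replaces each channel value `v` by `v ^ gamma`.  `gamma < 1` brightens,
#' `gamma > 1` darkens; 0 and 1 are fixed points.
#'
#' @param img a `raster_image`.
#' @param gamma positive exponent.
#' @return a `raster_image` of the same dimensions.
#' @export
gamma_correct <- function(img, gamma) {
  assert_image(img)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a positive number", call. = FALSE)
  raster_image(unclass(img)^gamma)
}

#' Gaussian pre-smoothing
#'
#' Per-channel separable Gaussian convolution with reflective boundary
#' handling; the discrete kernel is truncated at 4 sigma and renormalized.
#' `sigma = 0` returns the input unchanged.
#'
#' @param img a `raster_image`.
#' @param sigma nonnegative standard deviation in pixels.
#' @return a `raster_image`.
#' @export
gaussian_smooth <- function(img, sigma) {
  assert_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a nonnegative number", call. = FALSE)
  if (sigma == 0) return(img)
  rad <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- unclass(img)
  h <- dim(out)[1]; w <- dim(out)[2]
  for (ch in 1:3) {
    m <- matrix(out[, , ch], h, w)
    for (j in seq_len(w)) m[, j] <- convolve_reflect(m[, j], k)  # down cols
    for (i in seq_len(h)) m[i, ] <- convolve_reflect(m[i, ], k)  # across rows
    out[, , ch] <- m
  }
  raster_image(pmin(pmax(out, 0), 1))
}

# 1-D convolution with reflective (mirror-without-repeat falls back to
# repeat-edge for short signals) padding
convolve_reflect <- function(v, kernel) {
  rad <- (length(kernel) - 1L) %/% 2L
  n <- length(v)
  idx <- seq(1L - rad, n + rad)
  # reflect indices into [1, n]: 0 -> 1, -1 -> 2, n+1 -> n, ...
  idx <- ifelse(idx < 1L, 1L - idx + 1L, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  idx <- pmin(pmax(idx, 1L), n)
  padded <- v[idx]
  vapply(seq_len(n), function(i) sum(padded[i:(i + 2L * rad)] * kernel),
         numeric(1))
}

#' Rectangular region
#'
#' Half-open, 0-based region `[top, bottom) x [left, right)` in row/column
#' coordinates.
#'
#' @param top,left inclusive 0-based start row/column.
#' @param bottom,right exclusive end row/column.
#' @return a `rect`.
#' @export
rect <- function(top, left, bottom, right) {
  v <- c(top = top, left = left, bottom = bottom, right = right)
  if (anyNA(v) || any(v != floor(v)))
    stop("rect coordinates must be integers", call. = FALSE)
  if (top < 0 || left < 0 || bottom <= top || right <= left)
    stop("rect must satisfy 0 <= top < bottom and 0 <= left < right",
         call. = FALSE)
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "rect")
}

#' @export
print.rect <- function(x, ...) {
  cat(sprintf("<rect rows [%d,%d) x cols [%d,%d)>\n",
              x$top, x$bottom, x$left, x$right))
  invisible(x)
}

rect_dim <- function(r) c(r$bottom - r$top, r$right - r$left)

full_rect <- function(img) {
  d <- image_dim(img)
  rect(0L, 0L, d[1], d[2])
}

assert_rect_in <- function(region, height, width) {
  if (!inherits(region, "rect")) stop("expected a `rect`", call. = FALSE)
  if (region$bottom > height || region$right > width)
    stop(sprintf("rect [%d,%d)x[%d,%d) exceeds %d x %d image",
                 region$top, region$bottom, region$left, region$right,
                 height, width), call. = FALSE)
  invisible(region)
}

#' Extract a rectangular sub-image (zoom region)
#'
#' Returns the sub-image over rows `[top, bottom)` and columns
#' `[left, right)` with no resampling; zooming is modeled as cropping
#' followed by re-segmentation of the crop.
#'
#' @param img a `raster_image`.
#' @param region a [rect()] within the image bounds.
#' @return a `raster_image` of dimensions `(bottom - top, right - left)`.
#' @export
crop <- function(img, region) {
  assert_image(img)
  d <- image_dim(img)
  assert_rect_in(region, d[1], d[2])
  raster_image(unclass(img)[(region$top + 1L):region$bottom,
                            (region$left + 1L):region$right, , drop = FALSE])
}
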