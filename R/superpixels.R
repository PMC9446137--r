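#' Superpixel proposal parameters
#'
#' Parameter bundles for the three superpixel generators.  Each constructor
#' validates its arguments and returns a tagged list consumed by the
#' corresponding `*_segment()` function and by [propose()].
#'
#' @param scale_k positive constant of the region-merging threshold
#'   `tau(C) = scale_k / |C|`: larger values merge more aggressively and
#'   yield larger segments.
#' @param sigma nonnegative Gaussian pre-smoothing bandwidth in pixels.
#' @param min_size minimum final segment size in pixels; smaller components
#'   are merged into their most similar neighbor.
#' @return a parameter object.
#' @export
felz_params <- function(scale_k = 100, sigma = 0.8, min_size = 20L) {
  stopifnot(is.numeric(scale_k), length(scale_k) == 1L, scale_k > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(min_size), length(min_size) == 1L, min_size >= 1)
  structure(list(scale_k = scale_k, sigma = sigma,
                 min_size = as.integer(min_size)),
            class = c("felz_params", "segment_params"))
}

#' @rdname felz_params
#' @param n_segments requested number of clusters; seeds are laid out on a
#'   regular grid with spacing `S = sqrt(H * W / n_segments)`.
#' @param compactness spatial-versus-color weight `m` in the distance
#'   `D = sqrt(d_lab^2 + (m / S)^2 d_xy^2)`; larger values give more
#'   regular, grid-like segments.
#' @param max_iter maximum assign/update sweeps.
#' @param enforce_connectivity reassign stray 4-connected fragments smaller
#'   than `S^2 / 4` to an adjacent segment.
#' @export
slic_params <- function(n_segments = 100L, compactness = 10, max_iter = 10L,
                        enforce_connectivity = TRUE) {
  stopifnot(is.numeric(n_segments), length(n_segments) == 1L, n_segments >= 1,
            is.numeric(compactness), length(compactness) == 1L, compactness > 0,
            is.numeric(max_iter), length(max_iter) == 1L, max_iter >= 1,
            is.logical(enforce_connectivity), length(enforce_connectivity) == 1L)
  structure(list(n_segments = as.integer(n_segments),
                 compactness = compactness, max_iter = as.integer(max_iter),
                 enforce_connectivity = enforce_connectivity),
            class = c("slic_params", "segment_params"))
}

#' @rdname felz_params
#' @param kernel_size positive Parzen density bandwidth in the joint
#'   feature space.
#' @param max_dist maximum spatial linking distance in pixels; segment
#'   count is non-increasing in `max_dist`.
#' @param ratio color-versus-space scaling in `(0, 1]` applied to the Lab
#'   coordinates of the feature vector.
#' @export
quickshift_params <- function(kernel_size = 5, max_dist = 10, ratio = 1) {
  stopifnot(is.numeric(kernel_size), length(kernel_size) == 1L, kernel_size > 0,
            is.numeric(max_dist), length(max_dist) == 1L, max_dist > 0,
            is.numeric(ratio), length(ratio) == 1L, ratio > 0, ratio <= 1)
  structure(list(kernel_size = kernel_size, max_dist = max_dist, ratio = ratio),
            class = c("quickshift_params", "segment_params"))
}

new_superpixel_map <- function(labels, region = NULL) {
  structure(labels, class = c("superpixel_map", "matrix", "array"),
            region = region)
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map %d x %d, %d segments>\n",
              nrow(x), ncol(x), n_segments(x)))
  invisible(x)
}

#' Number of segments in a superpixel map
#' @param sp a `superpixel_map` (integer labels `0 .. n - 1`).
#' @return the number of distinct segment ids.
#' @export
n_segments <- function(sp) max(sp) + 1L

#' Felzenszwalb efficient graph-based segmentation
#'
#' Builds the 4-connected grid graph over the Gaussian-smoothed RGB pixels
#' with Euclidean color edge weights and merges components greedily in
#' nondecreasing edge-weight order.  An edge of weight `w` merges components
#' `C1`, `C2` when `w <= min(Int(Ci) + scale_k / |Ci|)`, where `Int(C)` is
#' the largest edge weight already merged inside `C` (the pairwise region
#' comparison predicate: component difference is the minimum-weight
#' connecting edge).  Components smaller than `min_size` are then merged
#' into their most similar neighbor.  Equal-weight edges are ordered by
#' their row-major endpoint indices, so the output is deterministic.
#'
#' @param img a `raster_image`.
#' @param params a [felz_params()].
#' @return a `superpixel_map` with contiguous ids `0 .. n - 1`; every
#'   segment is 4-connected and (for images of at least `min_size` pixels)
#'   at least `min_size` pixels.
#' @export
felzenszwalb_segment <- function(img, params = felz_params()) {
  assert_image(img)
  stopifnot(inherits(params, "felz_params"))
  sm <- gaussian_smooth(img, params$sigma)
  labels <- .felzenszwalb_cpp(unclass(sm), params$scale_k, params$min_size)
  new_superpixel_map(labels)
}

#' SLIC superpixels
#'
#' Local k-means clustering in the 5-D space of CIELAB color and pixel
#' coordinates.  Cluster centers start on a regular grid with spacing
#' `S = sqrt(H * W / n_segments)`, each perturbed to the lowest-gradient
#' pixel of its 3x3 neighborhood; pixels are repeatedly assigned to the
#' nearest center whose `2S x 2S` window covers them (a pixel may always
#' keep its current center) under
#' `D = sqrt(d_lab^2 + (compactness / S)^2 d_xy^2)`, and each center is
#' recomputed as the mean labxy vector of its pixels, until assignments are
#' stable or `max_iter` sweeps.  The per-sweep total of `D^2` is returned
#' as `attr(, "objective")` and is non-increasing.
#'
#' @param img a `raster_image`.
#' @param params a [slic_params()].
#' @return a `superpixel_map`; with `enforce_connectivity` every segment is
#'   4-connected.
#' @export
slic_segment <- function(img, params = slic_params()) {
  assert_image(img)
  stopifnot(inherits(params, "slic_params"))
  d <- image_dim(img)
  if (params$n_segments > prod(d))
    stop("`n_segments` exceeds the pixel count", call. = FALSE)
  res <- .slic_cpp(unclass(to_lab(img)), params$n_segments, params$compactness,
                   params$max_iter, params$enforce_connectivity)
  out <- new_superpixel_map(res$labels)
  attr(out, "objective") <- res$objective
  out
}

#' Quickshift superpixels
#'
#' Mode seeking in the joint feature space of ratio-scaled CIELAB color and
#' pixel coordinates.  Each pixel receives a Parzen density estimate
#' (Gaussian kernel of bandwidth `kernel_size`, summed over a square
#' spatial window of half-width `ceil(3 * kernel_size)`) and links to the
#' spatially nearest pixel of strictly higher density within `max_dist`;
#' pixels with no such neighbor are roots, and segments are the trees of
#' the resulting forest.  On exactly constant regions no pixel has strictly
#' higher density than another, so every plateau pixel becomes a root.
#'
#' @param img a `raster_image`.
#' @param params a [quickshift_params()].
#' @return a `superpixel_map`; `attr(, "parent")` and `attr(, "density")`
#'   expose the link forest (row-major, 0-based; a root is its own parent).
#' @export
quickshift_segment <- function(img, params = quickshift_params()) {
  assert_image(img)
  stopifnot(inherits(params, "quickshift_params"))
  labels <- .quickshift_cpp(unclass(to_lab(img)), params$ratio,
                            params$kernel_size, params$max_dist)
  new_superpixel_map(labels)
}
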