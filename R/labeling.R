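#' Label maps
#'
#' A `label_map` is an integer matrix of per-pixel tissue-class ids;
#' 0 means unlabeled, 1..C are palette classes.
#'
#' @param labels integer matrix of class ids.
#' @param palette the `tissue_palette` the ids refer to.
#' @return a `label_map`.
#' @export
label_map <- function(labels, palette) {
  stopifnot(is.matrix(labels), inherits(palette, "tissue_palette"))
  if (anyNA(labels) || min(labels) < 0 || max(labels) > nrow(palette))
    stop("label values must be 0 (unlabeled) or palette ids", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(labels, class = c("label_map", "matrix", "array"),
            palette = palette)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map %d x %d, %d unlabeled px>\n",
              nrow(x), ncol(x), sum(x == 0L)))
  invisible(x)
}

#' Start a labeling session
#'
#' A session holds the working image (mutated by scripted gamma
#' correction), the growing label mask, the palette, the active zoom
#' region and the cache of segmentation proposals.  All coordinates are
#' 0-based and row/column ordered; regions are half-open.
#'
#' @param img a `raster_image`.
#' @param palette a [tissue_palette()]; defaults to the five wound-tissue
#'   classes.
#' @return a `wound_session` (an environment: operations mutate it in
#'   place and return counts of pixels written).
#' @export
new_session <- function(img, palette = default_palette()) {
  assert_image(img)
  if (!inherits(palette, "tissue_palette") || NROW(palette) < 1L)
    stop("`palette` must be a non-empty tissue_palette", call. = FALSE)
  d <- image_dim(img)
  s <- new.env(parent = emptyenv())
  s$original <- img
  s$image <- img
  s$mask <- label_map(matrix(0L, d[1], d[2]), palette)
  s$palette <- palette
  s$region <- full_rect(img)
  s$proposals <- list()
  s$proposal_keys <- character(0)
  class(s) <- "wound_session"
  s
}

#' @export
print.wound_session <- function(x, ...) {
  d <- image_dim(x$image)
  cat(sprintf(
    "<wound_session %d x %d, %d classes, %d proposals, %d px labeled>\n",
    d[1], d[2], nrow(x$palette), length(x$proposals), sum(x$mask != 0L)))
  invisible(x)
}

assert_session <- function(s) {
  if (!inherits(s, "wound_session")) stop("expected a `wound_session`",
                                          call. = FALSE)
  invisible(s)
}

#' Session parameter actions
#'
#' `set_gamma()` gamma-corrects the session's working image (affecting all
#' subsequent proposals and wand fills); `set_region()` restricts
#' subsequent proposals to a rectangular zoom region, recomputed at full
#' resolution on the crop.
#'
#' @param session a `wound_session`.
#' @param gamma positive gamma exponent applied to the working image.
#' @return the session, invisibly.
#' @export
set_gamma <- function(session, gamma) {
  assert_session(session)
  session$image <- gamma_correct(session$image, gamma)
  invisible(session)
}

#' @rdname set_gamma
#' @param region a [rect()] inside the image, or `NULL` for the full frame.
#' @export
set_region <- function(session, region = NULL) {
  assert_session(session)
  if (is.null(region)) region <- full_rect(session$image)
  d <- image_dim(session$image)
  assert_rect_in(region, d[1], d[2])
  session$region <- region
  invisible(session)
}

proposal_key <- function(algorithm, params, region) {
  paste(algorithm,
        paste(names(params), vapply(params, format, ""), sep = "=",
              collapse = ","),
        sprintf("[%d,%d)x[%d,%d)", region$top, region$bottom, region$left,
                region$right))
}

#' Generate (and cache) a segmentation proposal
#'
#' Runs the requested segmenter on the crop of the working image defined
#' by the active region and stores the result in the session.  Proposals
#' are keyed by (algorithm, parameters, region): repeating an identical
#' call returns the cached partition; changing any hyperparameter yields a
#' new stored proposal.
#'
#' @param session a `wound_session`.
#' @param algorithm one of `"felzenszwalb"`, `"slic"`, `"quickshift"`,
#'   `"kmeans"`.
#' @param params the matching parameter object ([felz_params()],
#'   [slic_params()], [quickshift_params()], [kmeans_params()]); `NULL`
#'   uses that algorithm's defaults.
#' @return a `superpixel_map` whose `"region"` attribute records the
#'   sub-image it partitions and whose `"index"` attribute is its 1-based
#'   position in `session$proposals`.
#' @export
propose <- function(session, algorithm = c("felzenszwalb", "slic",
                                           "quickshift", "kmeans"),
                    params = NULL) {
  assert_session(session)
  algorithm <- match.arg(algorithm)
  if (is.null(params))
    params <- switch(algorithm, felzenszwalb = felz_params(),
                     slic = slic_params(), quickshift = quickshift_params(),
                     kmeans = kmeans_params())
  wanted <- switch(algorithm, felzenszwalb = "felz_params",
                   slic = "slic_params", quickshift = "quickshift_params",
                   kmeans = "kmeans_params")
  if (!inherits(params, wanted))
    stop(sprintf("`params` must be a %s for algorithm '%s'", wanted,
                 algorithm), call. = FALSE)
  key <- proposal_key(algorithm, params, session$region)
  hit <- match(key, session$proposal_keys)
  if (!is.na(hit)) return(session$proposals[[hit]])
  sub <- crop(session$image, session$region)
  sp <- switch(algorithm,
               felzenszwalb = felzenszwalb_segment(sub, params),
               slic = slic_segment(sub, params),
               quickshift = quickshift_segment(sub, params),
               kmeans = kmeans_segment(sub, params))
  attr(sp, "region") <- session$region
  attr(sp, "algorithm") <- algorithm
  session$proposals <- c(session$proposals, list(sp))
  session$proposal_keys <- c(session$proposal_keys, key)
  attr(sp, "index") <- length(session$proposals)
  session$proposals[[length(session$proposals)]] <- sp
  sp
}

resolve_proposal <- function(session, proposal) {
  if (inherits(proposal, "superpixel_map")) return(proposal)
  if (is.numeric(proposal) && length(proposal) == 1L &&
      proposal >= 1 && proposal <= length(session$proposals))
    return(session$proposals[[proposal]])
  stop("`proposal` must be a superpixel_map or a stored proposal index",
       call. = FALSE)
}

#' Paint one proposal segment into the mask
#'
#' Sets every pixel of the segment (offset by the proposal's region) to
#' the given tissue class, overwriting previous labels.  For k-means
#' proposals a "segment" is one color cluster; use
#' [split_connected_components()] first for spatially local selection.
#'
#' @param session a `wound_session`.
#' @param proposal a `superpixel_map` from [propose()], or its 1-based
#'   index in `session$proposals`.
#' @param segment_id segment id present in the proposal (0-based).
#' @param class_ref palette class id or name.
#' @return the number of pixels written.
#' @export
select_segment <- function(session, proposal, segment_id, class_ref) {
  assert_session(session)
  proposal <- resolve_proposal(session, proposal)
  cid <- class_id(session$palette, class_ref)
  if (!(segment_id %in% 0:(n_segments(proposal) - 1L)))
    stop("segment id ", segment_id, " not present in proposal", call. = FALSE)
  region <- attr(proposal, "region")
  if (is.null(region)) region <- full_rect(session$image)
  sel <- which(unclass(proposal) == segment_id, arr.ind = TRUE)
  rows <- sel[, 1] + region$top
  cols <- sel[, 2] + region$left
  m <- unclass(session$mask)
  m[cbind(rows, cols)] <- cid
  session$mask <- label_map(m, session$palette)
  nrow(sel)
}

#' Brush correction
#'
#' Paints a disc of the given radius (Euclidean distance on the pixel
#' grid, clipped to the image) with a tissue class.
#'
#' @param session a `wound_session`.
#' @param center `c(row, col)`, 0-based, inside the image.
#' @param radius nonnegative radius in pixels; radius 0 paints the single
#'   center pixel.
#' @param class_ref palette class id or name.
#' @return the number of pixels written.
#' @export
brush <- function(session, center, radius, class_ref) {
  assert_session(session)
  cid <- class_id(session$palette, class_ref)
  d <- image_dim(session$image)
  r0 <- center[1]; c0 <- center[2]
  if (length(center) != 2L || r0 < 0 || c0 < 0 || r0 >= d[1] || c0 >= d[2])
    stop("`center` must be 0-based (row, col) inside the image", call. = FALSE)
  if (radius < 0) stop("`radius` must be nonnegative", call. = FALSE)
  rr <- max(0, floor(r0 - radius)):min(d[1] - 1, ceiling(r0 + radius))
  cc <- max(0, floor(c0 - radius)):min(d[2] - 1, ceiling(c0 + radius))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - r0)^2 + (g$col - c0)^2 <= radius^2
  m <- unclass(session$mask)
  m[cbind(g$row[keep] + 1L, g$col[keep] + 1L)] <- cid
  session$mask <- label_map(m, session$palette)
  sum(keep)
}

#' Magic-wand correction
#'
#' Flood-fills from a seed pixel over 4-connectivity, admitting every
#' pixel whose RGB Euclidean distance to the seed pixel is at most
#' `tolerance`, and paints the admitted (connected) set with a tissue
#' class.  Similarity is measured on the working image against the seed
#' pixel, not a running region mean.
#'
#' @param session a `wound_session`.
#' @param seed `c(row, col)`, 0-based, inside the image.
#' @param tolerance nonnegative RGB distance threshold (channel scale
#'   `[0, 1]`, so the black-to-white distance is `sqrt(3)`).
#' @param class_ref palette class id or name.
#' @return the number of pixels written.
#' @export
magic_wand <- function(session, seed, tolerance, class_ref) {
  assert_session(session)
  cid <- class_id(session$palette, class_ref)
  d <- image_dim(session$image)
  if (length(seed) != 2L || seed[1] < 0 || seed[2] < 0 ||
      seed[1] >= d[1] || seed[2] >= d[2])
    stop("`seed` must be 0-based (row, col) inside the image", call. = FALSE)
  if (tolerance < 0) stop("`tolerance` must be nonnegative", call. = FALSE)
  sel <- .floodfill_cpp(unclass(session$image), as.integer(seed[1]),
                        as.integer(seed[2]), tolerance)
  m <- unclass(session$mask)
  m[sel] <- cid
  session$mask <- label_map(m, session$palette)
  sum(sel)
}

#' Split a proposal into connected components
#'
#' K-means clusters may be spatially disconnected; this re-labels every
#' 4-connected component of every segment as its own segment so that
#' selection stays spatially local.
#'
#' @param sp a `superpixel_map`.
#' @return a `superpixel_map` with 4-connected segments, same region.
#' @export
split_connected_components <- function(sp) {
  stopifnot(inherits(sp, "superpixel_map"))
  out <- connected_components(unclass(sp))
  res <- new_superpixel_map(out, region = attr(sp, "region"))
  attr(res, "region") <- attr(sp, "region")
  res
}

# label each 4-connected constant-value component, ids contiguous in
# row-major first-occurrence order (pure R; used on proposal-sized inputs)
connected_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  comp <- matrix(-1L, h, w)
  nxt <- 0L
  # row-major scan
  for (r0 in seq_len(h)) {
    for (c0 in seq_len(w)) {
      if (comp[r0, c0] >= 0L) next
      val <- m[r0, c0]
      queue <- matrix(c(r0, c0), 1)
      comp[r0, c0] <- nxt
      while (nrow(queue) > 0) {
        p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          r <- p[1] + dd[1]; c <- p[2] + dd[2]
          if (r < 1L || r > h || c < 1L || c > w) next
          if (comp[r, c] < 0L && m[r, c] == val) {
            comp[r, c] <- nxt
            queue <- rbind(queue, c(r, c))
          }
        }
      }
      nxt <- nxt + 1L
    }
  }
  comp
}

#' Save the image/label pair
#'
#' Writes `<stem>.png` (the original photograph), `<stem>_label.png`
#' (an 8-bit indexed PNG whose palette index equals the class id; index 0,
#' rendered white, is reserved for unlabeled) and `<stem>_palette.json`
#' mapping ids to names and display colors.
#'
#' @param session a `wound_session`.
#' @param stem output path stem.
#' @param allow_unlabeled if `FALSE` (default), refuse to save a mask that
#'   still contains unlabeled pixels.
#' @return character vector of the two image paths, invisibly.
#' @export
save_pair <- function(session, stem, allow_unlabeled = FALSE) {
  assert_session(session)
  n0 <- sum(session$mask == 0L)
  if (!allow_unlabeled && n0 > 0L)
    stop(sprintf("mask is incomplete: %d unlabeled pixel(s)", n0),
         call. = FALSE)
  img_path <- paste0(stem, ".png")
  lab_path <- paste0(stem, "_label.png")
  save_image(session$original, img_path)
  pal <- rbind(c(255L, 255L, 255L), palette_color_matrix(session$palette))
  write_indexed_png(unclass(session$mask), pal, lab_path)
  sidecar <- list(classes = lapply(seq_len(nrow(session$palette)), function(i)
    list(id = session$palette$id[i], name = session$palette$name[i],
         color = c(session$palette$r[i], session$palette$g[i],
                   session$palette$b[i]))))
  jsonlite::write_json(sidecar, paste0(stem, "_palette.json"),
                       auto_unbox = TRUE)
  invisible(c(img_path, lab_path))
}

#' Load a label mask written by [save_pair()]
#'
#' @param path path to the indexed label PNG.
#' @param palette the palette the mask was written with.
#' @return a `label_map`.
#' @export
load_label_map <- function(path, palette = default_palette()) {
  res <- read_indexed_png(path)
  label_map(res$indices, palette)
}
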