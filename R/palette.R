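#' Tissue class palettes
#'
#' A `tissue_palette` is an ordered set of tissue classes mapping class id
#' (1..C) to a name and a display color; id 0 is reserved for "unlabeled".
#'
#' The default five-class set covers wound photographs: intact skin
#' (green), granulation (red), slough (yellow), necrotic (black) and
#' background (blue).  The `"intro"` preset swaps intact skin to blue
#' (with background gray), an alternative convention used when masks are
#' painted in a general-purpose image editor.
#'
#' @param names character vector of unique class names (class ids are their
#'   positions, starting at 1).
#' @param colors `C x 3` integer matrix of display RGB values in 0..255,
#'   one row per class; rows must be unique.
#' @return a `tissue_palette` tibble with columns `id`, `name`, `r`, `g`,
#'   `b`.
#' @export
tissue_palette <- function(names, colors) {
  if (length(names) < 1L) stop("palette needs at least one class", call. = FALSE)
  colors <- as.matrix(colors)
  if (nrow(colors) != length(names) || ncol(colors) != 3L)
    stop("`colors` must be a length(names) x 3 RGB matrix", call. = FALSE)
  if (anyDuplicated(names)) stop("class names must be unique", call. = FALSE)
  if (anyDuplicated(colors)) stop("class colors must be unique", call. = FALSE)
  if (min(colors) < 0 || max(colors) > 255 || any(colors != floor(colors)))
    stop("colors must be integers in 0..255", call. = FALSE)
  structure(tibble::tibble(id = seq_along(names), name = as.character(names),
                           r = as.integer(colors[, 1]),
                           g = as.integer(colors[, 2]),
                           b = as.integer(colors[, 3])),
            class = c("tissue_palette", "tbl_df", "tbl", "data.frame"))
}

#' @rdname tissue_palette
#' @param preset `"default"` (intact skin green, per the labeled-output
#'   convention) or `"intro"` (intact skin blue, background gray).
#' @export
default_palette <- function(preset = c("default", "intro")) {
  preset <- match.arg(preset)
  if (preset == "default") {
    tissue_palette(
      c("intact_skin", "granulation", "slough", "necrotic", "background"),
      rbind(c(0, 255, 0), c(255, 0, 0), c(255, 255, 0), c(0, 0, 0),
            c(0, 0, 255)))
  } else {
    tissue_palette(
      c("intact_skin", "granulation", "slough", "necrotic", "background"),
      rbind(c(0, 0, 255), c(255, 0, 0), c(255, 255, 0), c(0, 0, 0),
            c(128, 128, 128)))
  }
}

#' Resolve a class reference to its palette id
#' @param palette a `tissue_palette`.
#' @param class_ref a class id (1..C) or class name.
#' @return the integer class id.
#' @export
class_id <- function(palette, class_ref) {
  stopifnot(inherits(palette, "tissue_palette"))
  if (is.character(class_ref)) {
    i <- match(class_ref, palette$name)
    if (is.na(i)) stop("unknown class name: ", class_ref, call. = FALSE)
    return(palette$id[i])
  }
  if (!is.numeric(class_ref) || length(class_ref) != 1L ||
      !(class_ref %in% palette$id))
    stop("unknown class id: ", class_ref, call. = FALSE)
  as.integer(class_ref)
}

palette_color_matrix <- function(palette) {
  m <- cbind(palette$r, palette$g, palette$b)
  rownames(m) <- palette$name
  m
}
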