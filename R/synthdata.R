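#' Synthetic wound-scene parameters
#'
#' The generator emulates the structure of a clinical wound photograph:
#' a background plane, a skin ellipse covering at least 40% of the frame,
#' and a wound bed bounded by a closed curve
#' `r(theta) = R * (1 + irregularity * sum_k k^-1 cos(k theta + phi_k))`
#' (k = 2..5, seeded phases), whose interior is granulation tissue with
#' embedded slough and necrotic blobs built as unions of seeded discs.
#' Per-pixel color is the class mean plus Gaussian noise, optionally
#' modulated by a linear illumination gradient across columns.
#'
#' @param height,width scene dimensions in pixels (at least 32 x 32).
#' @param seed integer seed; a fixed seed gives a bit-identical scene.
#' @param class_colors named list of mean RGB triplets in `[0, 1]` for
#'   `background`, `intact_skin`, `granulation`, `slough`, `necrotic`.
#' @param noise_sd per-channel Gaussian color noise standard deviation.
#' @param wound_radius_frac range (length 2) of the wound base radius as a
#'   fraction of `min(height, width)`.
#' @param irregularity nonnegative amplitude of the radial boundary
#'   perturbation (0 gives a circle).
#' @param illumination amplitude in `[0, 1]` of the linear illumination
#'   gradient (0 disables it).
#' @param include_slough,include_necrotic whether the wound bed contains
#'   slough / necrotic blobs.
#' @return a `scene_params` list.
#' @export
scene_params <- function(height = 128L, width = 128L, seed = 1L,
                         class_colors = list(
                           background = c(0.45, 0.50, 0.58),
                           intact_skin = c(0.80, 0.62, 0.48),
                           granulation = c(0.70, 0.20, 0.22),
                           slough = c(0.82, 0.72, 0.30),
                           necrotic = c(0.12, 0.08, 0.07)),
                         noise_sd = 0.035,
                         wound_radius_frac = c(0.18, 0.30),
                         irregularity = 0.2, illumination = 0.1,
                         include_slough = TRUE, include_necrotic = TRUE) {
  stopifnot(height >= 32, width >= 32, length(wound_radius_frac) == 2L,
            all(wound_radius_frac > 0), all(wound_radius_frac < 0.5),
            noise_sd >= 0, irregularity >= 0,
            illumination >= 0, illumination <= 1)
  needed <- c("background", "intact_skin", "granulation", "slough", "necrotic")
  stopifnot(all(needed %in% names(class_colors)),
            all(vapply(class_colors, function(x)
              length(x) == 3L && min(x) >= 0 && max(x) <= 1, TRUE)))
  structure(list(height = as.integer(height), width = as.integer(width),
                 seed = as.integer(seed), class_colors = class_colors,
                 noise_sd = noise_sd, wound_radius_frac = wound_radius_frac,
                 irregularity = irregularity, illumination = illumination,
                 include_slough = include_slough,
                 include_necrotic = include_necrotic),
            class = "scene_params")
}

#' Generate a synthetic wound scene with ground truth
#'
#' @param params a [scene_params()].
#' @return a `synthetic_scene`: list with `image` (a `raster_image`),
#'   `truth` (a fully labeled `label_map` over [default_palette()]) and
#'   `params`.  Deterministic for a fixed seed; every enabled class
#'   occupies at least one pixel.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  pal <- default_palette()
  id <- function(nm) pal$id[match(nm, pal$name)]
  H <- params$height; W <- params$width
  withr::with_seed(params$seed, {
    rows <- matrix(0:(H - 1), H, W)
    cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
    truth <- matrix(id("background"), H, W)

    # skin ellipse: semi-axes 0.42..0.48 of the half-extent keep it inside
    # the frame, so its area is >= pi * 0.42^2 ~ 55% of the frame
    cy <- (H - 1) / 2 + stats::runif(1, -0.02, 0.02) * H
    cx <- (W - 1) / 2 + stats::runif(1, -0.02, 0.02) * W
    a <- stats::runif(1, 0.42, 0.48) * W
    b <- stats::runif(1, 0.42, 0.48) * H
    in_skin <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1
    truth[in_skin] <- id("intact_skin")

    # wound bed: irregular closed curve around a jittered center
    R <- stats::runif(1, params$wound_radius_frac[1],
                      params$wound_radius_frac[2]) * min(H, W)
    wy <- cy + stats::runif(1, -0.08, 0.08) * H
    wx <- cx + stats::runif(1, -0.08, 0.08) * W
    phases <- stats::runif(4, 0, 2 * pi)
    theta <- atan2(rows - wy, cols - wx)
    rad <- R
    for (k in 2:5)
      rad <- rad + R * params$irregularity * cos(k * theta + phases[k - 1]) / k
    dist <- sqrt((rows - wy)^2 + (cols - wx)^2)
    in_wound <- dist <= rad & in_skin
    truth[in_wound] <- id("granulation")

    wound_px <- which(in_wound)
    blob_union <- function(n_discs, r_range) {
      m <- matrix(FALSE, H, W)
      if (length(wound_px) == 0L) return(m)
      centers <- sample(wound_px, n_discs, replace = TRUE)
      radii <- stats::runif(n_discs, r_range[1], r_range[2]) * R
      for (i in seq_len(n_discs)) {
        br <- (centers[i] - 1) %% H
        bc <- (centers[i] - 1) %/% H
        m <- m | (rows - br)^2 + (cols - bc)^2 <= radii[i]^2
      }
      m & in_wound
    }
    if (params$include_slough)
      truth[blob_union(sample(3:5, 1), c(0.15, 0.35))] <- id("slough")
    if (params$include_necrotic)
      truth[blob_union(sample(2:4, 1), c(0.10, 0.25))] <- id("necrotic")

    # rasterization guard: every enabled class keeps at least one pixel
    enabled <- c("background", "intact_skin", "granulation",
                 if (params$include_slough) "slough",
                 if (params$include_necrotic) "necrotic")
    for (nm in enabled) {
      if (!any(truth == id(nm))) {
        donor <- which(truth == id("granulation"))
        if (length(donor) == 0L) donor <- which(truth == id("intact_skin"))
        truth[donor[ceiling(length(donor) / 2)]] <- id(nm)
      }
    }

    img <- array(0, dim = c(H, W, 3))
    for (nm in names(params$class_colors)) {
      px <- truth == id(nm)
      if (!any(px)) next
      mu <- params$class_colors[[nm]]
      for (ch in 1:3)
        img[, , ch][px] <- mu[ch] + stats::rnorm(sum(px), 0, params$noise_sd)
    }
    if (params$illumination > 0) {
      grad <- 1 + params$illumination * ((cols / max(W - 1, 1)) - 0.5)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = raster_image(img),
                   truth = label_map(truth, pal), params = params),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d x %d, seed %d>\n", x$params$height,
              x$params$width, x$params$seed))
  invisible(x)
}

#' The pinned fixture scenes
#'
#' Six seeded scenes spanning the generator's regimes: with and without
#' necrotic tissue, low and high color noise, low and high boundary
#' irregularity.  Used throughout the test suite and by the acceptance
#' pipeline.
#'
#' @param height,width scene size.
#' @param seed_base seeds are `seed_base + 1 .. seed_base + 6`.
#' @return a list of six `synthetic_scene`s.
#' @export
fixture_scenes <- function(height = 128L, width = 128L, seed_base = 100L) {
  cfg <- list(
    list(necrotic = TRUE,  noise = 0.02, irr = 0.10),
    list(necrotic = FALSE, noise = 0.02, irr = 0.10),
    list(necrotic = TRUE,  noise = 0.06, irr = 0.10),
    list(necrotic = FALSE, noise = 0.06, irr = 0.35),
    list(necrotic = TRUE,  noise = 0.02, irr = 0.35),
    list(necrotic = FALSE, noise = 0.06, irr = 0.10))
  lapply(seq_along(cfg), function(i)
    generate_scene(scene_params(height = height, width = width,
                                seed = seed_base + i,
                                noise_sd = cfg[[i]]$noise,
                                irregularity = cfg[[i]]$irr,
                                include_necrotic = cfg[[i]]$necrotic)))
}

#' Perfect-user selection oracle
#'
#' Models an ideal second-stage user: every superpixel is assigned the
#' majority ground-truth class among its pixels (ties broken toward the
#' smallest class id).  The output is fully labeled and is the best
#' constant-per-segment approximation of the truth by pooled accuracy.
#'
#' @param proposal a `superpixel_map`.
#' @param truth a fully labeled `label_map` of the same dimensions.
#' @return a `label_map`.
#' @export
oracle_select <- function(proposal, truth) {
  if (!all(dim(proposal) == dim(truth)))
    stop("dimensions differ", call. = FALSE)
  seg <- as.vector(unclass(proposal))
  tr <- as.vector(unclass(truth))
  maj <- vapply(split(tr, seg), function(v) {
    tab <- tabulate(v, nbins = max(tr))
    which.max(tab)  # first (= smallest id) maximum
  }, integer(1))
  out <- matrix(maj[as.character(seg)], nrow(truth), ncol(truth))
  label_map(out, attr(truth, "palette"))
}

#' End-to-end achievable metrics for one proposal configuration
#'
#' Quantifies how closely selecting whole superpixels can approximate the
#' pixel-level truth: runs the segmenter on the scene image, lets the
#' perfect-user oracle label every segment, and scores the result against
#' the ground truth (pooled per-class metrics, all pixels labeled).
#'
#' @param scene a `synthetic_scene`.
#' @param algorithm segmentation algorithm name (see [propose()]).
#' @param params matching parameter object, or `NULL` for defaults.
#' @return the [class_metrics()] tibble, with the oracle labeling in
#'   `attr(, "labels")`.
#' @export
achievable_metrics <- function(scene, algorithm, params = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  session <- new_session(scene$image, attr(scene$truth, "palette"))
  sp <- propose(session, algorithm, params)
  labeled <- oracle_select(sp, scene$truth)
  cm <- confusion_matrix(labeled, scene$truth,
                         attr(scene$truth, "palette"))
  out <- suppressWarnings(class_metrics(cm))
  attr(out, "labels") <- labeled
  out
}
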