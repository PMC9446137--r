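test_that("sessions start unlabeled and validate their palette", {
  img <- rand_image(10, 10)
  s <- new_session(img)
  expect_equal(sum(unclass(s$mask) == 0L), 100L)
  expect_equal(class_id(s$palette, "granulation"), 2L)
  expect_error(class_id(s$palette, "bone"), "unknown class")
  expect_error(class_id(s$palette, 9), "unknown class")
  expect_error(new_session(img, palette = structure(list(),
                                                    class = "tissue_palette")),
               "non-empty")
  expect_error(tissue_palette(character(0), matrix(0, 0, 3)), "at least one")
  expect_error(tissue_palette(c("a", "a"), rbind(c(1, 2, 3), c(4, 5, 6))),
               "unique")
})

test_that("proposals are cached by algorithm, params and region", {
  img <- rand_image(16, 16)
  s <- new_session(img)
  p1 <- propose(s, "slic", slic_params(n_segments = 4))
  p2 <- propose(s, "slic", slic_params(n_segments = 4))
  expect_identical(unclass(p1), unclass(p2))
  expect_equal(length(s$proposals), 1L)
  p3 <- propose(s, "slic", slic_params(n_segments = 9))
  expect_equal(length(s$proposals), 2L)
  expect_false(identical(unclass(p1), unclass(p3)))
  # constant image, felzenszwalb -> single segment over the full frame
  sc <- new_session(raster_image(array(0.7, c(8, 8, 3))))
  pf <- propose(sc, "felzenszwalb", felz_params(scale_k = 1, sigma = 0,
                                                min_size = 1))
  expect_equal(n_segments(pf), 1L)
  # region-restricted proposal has the region's dimensions
  set_region(s, rect(0, 0, 16, 8))
  ph <- propose(s, "felzenszwalb")
  expect_equal(dim(unclass(ph)), c(16L, 8L))
  expect_error(propose(s, "slic", felz_params()), "slic_params")
})

test_that("select_segment writes the segment at its region offset", {
  img <- rand_image(12, 12)
  s <- new_session(img)
  # full-image proposal: count equals segment cardinality
  sp <- propose(s, "slic", slic_params(n_segments = 4))
  seg_size <- sum(unclass(sp) == 0L)
  n <- select_segment(s, sp, 0L, "slough")
  expect_equal(n, seg_size)
  expect_equal(sum(unclass(s$mask) == 3L), seg_size)
  # overwrite semantics: last class wins
  n2 <- select_segment(s, sp, 0L, "necrotic")
  expect_equal(n2, seg_size)
  expect_equal(sum(unclass(s$mask) == 3L), 0L)
  expect_equal(sum(unclass(s$mask) == 4L), seg_size)
  # proposal on a sub-region writes only inside that region
  set_region(s, rect(5, 0, 10, 12))
  spr <- propose(s, "felzenszwalb", felz_params(scale_k = 10, sigma = 0,
                                                min_size = 1))
  before <- unclass(s$mask)
  select_segment(s, spr, 0L, "background")
  changed <- which(unclass(s$mask) != before, arr.ind = TRUE)
  expect_true(all(changed[, 1] >= 6 & changed[, 1] <= 10))
  expect_error(select_segment(s, sp, 99L, 1L), "not present")
})

test_that("brush paints clipped Euclidean discs", {
  s <- new_session(rand_image(9, 9))
  expect_equal(brush(s, c(4, 4), 0, "granulation"), 1L)
  expect_equal(sum(unclass(s$mask) == 2L), 1L)
  # radius 1.5 at the center covers the 3x3 block (diagonals at sqrt(2))
  s2 <- new_session(rand_image(9, 9))
  expect_equal(brush(s2, c(4, 4), 1.5, 1L), 9L)
  expect_equal(which(unclass(s2$mask) == 1L, arr.ind = TRUE),
               as.matrix(expand.grid(row = 4:6, col = 4:6)),
               ignore_attr = TRUE)
  # corner clipping: radius 1 keeps 3 in-bounds pixels
  s3 <- new_session(rand_image(9, 9))
  expect_equal(brush(s3, c(0, 0), 1, 1L), 3L)
  expect_error(brush(s3, c(9, 0), 1, 1L), "inside the image")
  expect_error(brush(s3, c(1, 1), 1, "bone"), "unknown class")
})

test_that("magic wand floods the seed-connected similar region", {
  # tolerance 0 with all-different neighbors: only the seed
  set.seed(12)
  img <- rand_image(5, 5, grid8 = FALSE)
  s <- new_session(img)
  expect_equal(magic_wand(s, c(2, 2), 0, 1L), 1L)
  # constant image: everything
  s2 <- new_session(raster_image(array(0.2, c(6, 7, 3))))
  expect_equal(magic_wand(s2, c(3, 3), 0.001, "slough"), 42L)
  # the 4x4 worked example: 8 pixels of the seed's component
  g <- matrix(c(10, 10, 200, 200,
                10, 10, 200, 200,
                10, 200, 200, 200,
                10, 10, 10, 200) / 255, 4, 4, byrow = TRUE)
  s3 <- new_session(raster_image(array(rep(g, 3), c(4, 4, 3))))
  expect_equal(magic_wand(s3, c(0, 0), 0.1, 1L), 8L)
  got <- which(unclass(s3$mask) == 1L, arr.ind = TRUE) - 1L
  expect_equal(nrow(got), 8L)
  expect_false(any(got[, 1] == 2 & got[, 2] >= 1))  # (2,1..3) excluded
  expect_error(magic_wand(s3, c(4, 0), 0.1, 1L), "inside the image")
})

test_that("magic wand agrees with the breadth-first-search reference", {
  set.seed(13)
  for (i in 1:25) {
    img <- rand_image(16, 16)
    seed <- c(sample(0:15, 1), sample(0:15, 1))
    tol <- stats::runif(1, 0, 0.6)
    s <- new_session(img)
    n <- magic_wand(s, seed, tol, 1L)
    ref <- wand_oracle(img, seed, tol)
    expect_equal(unclass(s$mask) == 1L, ref, ignore_attr = TRUE)
    expect_equal(n, sum(ref))
  }
})

test_that("disjoint actions commute", {
  img <- rand_image(10, 10)
  s1 <- new_session(img); s2 <- new_session(img)
  brush(s1, c(1, 1), 1, 1L); brush(s1, c(8, 8), 1, 2L)
  brush(s2, c(8, 8), 1, 2L); brush(s2, c(1, 1), 1, 1L)
  expect_identical(unclass(s1$mask), unclass(s2$mask))
})

test_that("k-means proposals split into selectable connected components", {
  arr <- array(0, c(6, 6, 3))
  arr[1:2, 1:2, 1] <- 1
  arr[5:6, 5:6, 1] <- 1   # same color, two islands
  km <- kmeans_segment(raster_image(arr), kmeans_params(n_clusters = 2,
                                                        seed = 1))
  split <- split_connected_components(km)
  expect_equal(n_segments(split), 3L)
  expect_gt(n_segments(split), n_segments(km))
})

test_that("label PNG save/load round trip is bit-exact", {
  tmp <- withr::local_tempdir()
  img <- rand_image(14, 11)
  s <- new_session(img)
  brush(s, c(5, 5), 30, "background")  # cover everything
  brush(s, c(2, 2), 2, "granulation")
  paths <- save_pair(s, file.path(tmp, "sample"))
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(tmp, "sample_palette.json")))
  re <- load_label_map(paths[2], s$palette)
  expect_identical(unclass(re), unclass(s$mask))
  # libpng independently expands indices to the written palette colors
  arr <- png::readPNG(paths[2])
  px <- floor(arr[3, 3, 1:3] * 255 + 0.5)
  expect_equal(px, c(255, 0, 0))  # granulation renders red
  # and the original photograph round-trips at 8-bit precision
  orig <- load_image(paths[1])
  expect_equal(unclass(orig),
               floor(unclass(img) * 255 + 0.5) / 255, ignore_attr = TRUE)
})

test_that("incomplete masks are refused unless allowed", {
  tmp <- withr::local_tempdir()
  s <- new_session(rand_image(5, 5))
  brush(s, c(2, 2), 10, 1L)
  m <- unclass(s$mask); m[1, 1] <- 0L
  s$mask <- label_map(m, s$palette)
  expect_error(save_pair(s, file.path(tmp, "x")), "1 unlabeled")
  expect_silent(save_pair(s, file.path(tmp, "x"), allow_unlabeled = TRUE))
  re <- load_label_map(file.path(tmp, "x_label.png"))
  expect_equal(sum(unclass(re) == 0L), 1L)
})

test_that("scripts replay deterministically down to file bytes", {
  tmp <- withr::local_tempdir()
  img <- rand_image(24, 24)
  script <- list(
    list(op = "set_gamma", gamma = 0.8),
    list(op = "propose", algorithm = "slic", n_segments = 6),
    list(op = "select", proposal = 0, segment = 0, class = "background"),
    list(op = "select", proposal = 0, segment = 1, class = "intact_skin"),
    list(op = "set_region", top = 4, left = 4, bottom = 20, right = 20),
    list(op = "propose", algorithm = "felzenszwalb", scale_k = 0.5,
         sigma = 0, min_size = 4),
    list(op = "select", proposal = 1, segment = 0, class = "granulation"),
    list(op = "brush", row = 1, col = 1, radius = 2, class = "slough"),
    list(op = "wand", row = 22, col = 22, tolerance = 0.3,
         class = "necrotic"),
    list(op = "save", stem = file.path(tmp, "a"), allow_unlabeled = TRUE))
  res1 <- run_script(img, script)
  script[[10]]$stem <- file.path(tmp, "b")
  res2 <- run_script(img, script)
  expect_identical(unclass(res1$mask), unclass(res2$mask))
  expect_identical(readBin(file.path(tmp, "a_label.png"), "raw", 1e6),
                   readBin(file.path(tmp, "b_label.png"), "raw", 1e6))
  # scripts survive JSON serialization
  sp <- file.path(tmp, "script.json")
  write_session_script(script, sp)
  res3 <- run_script(img, sp)
  expect_identical(unclass(res3$mask), unclass(res2$mask))
  # empty script leaves everything unlabeled
  expect_equal(sum(unclass(run_script(img, list())$mask) == 0L), 24L * 24L)
  # first invalid action aborts with its index
  bad <- list(list(op = "brush", row = 1, col = 1, radius = 1, class = 1),
              list(op = "select", proposal = 5, segment = 0, class = 1))
  expect_error(run_script(img, bad), "action 2")
})
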