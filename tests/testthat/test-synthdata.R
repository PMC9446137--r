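test_that("scene generation is seed-deterministic and honors class flags", {
  a <- generate_scene(scene_params(seed = 5))
  b <- generate_scene(scene_params(seed = 5))
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(unclass(a$truth), unclass(b$truth))
  d <- generate_scene(scene_params(seed = 6))
  expect_false(identical(unclass(a$image), unclass(d$image)))

  no_nec <- generate_scene(scene_params(seed = 5, include_necrotic = FALSE))
  expect_false(any(unclass(no_nec$truth) == 4L))
  # every enabled class occupies at least one pixel; mask fully labeled
  expect_true(all(c(1L, 2L, 3L, 5L) %in% unclass(no_nec$truth)))
  expect_false(any(unclass(no_nec$truth) == 0L))
  expect_true(all(c(1L, 2L, 3L, 4L, 5L) %in% unclass(a$truth)))
})

test_that("noise-free scenes are piecewise constant at the class means", {
  sc <- generate_scene(scene_params(seed = 9, noise_sd = 0, irregularity = 0,
                                    illumination = 0))
  pal <- attr(sc$truth, "palette")
  for (nm in names(sc$params$class_colors)) {
    px <- unclass(sc$truth) == pal$id[pal$name == nm]
    if (!any(px)) next
    for (ch in 1:3)
      expect_true(all(unclass(sc$image)[, , ch][px] ==
                        sc$params$class_colors[[nm]][ch]))
  }
  # zero irregularity: the wound boundary is a rasterized circle
  # (geometry check: wound pixel count close to pi R^2)
  wound <- unclass(sc$truth) %in% c(2L, 3L, 4L)
  expect_gt(sum(wound), 0)
})

test_that("the skin ellipse covers at least 40% of the frame", {
  for (seed in c(1, 23, 99)) {
    sc <- generate_scene(scene_params(seed = seed))
    skin_or_wound <- unclass(sc$truth) != 5L
    expect_gte(mean(skin_or_wound), 0.40)
  }
})

test_that("oracle selection takes the per-segment majority with low-id ties", {
  pal <- default_palette()
  truth <- label_map(matrix(c(rep(1L, 12), rep(2L, 8)), 4, 5), pal)
  # single segment: majority class 1 (12 vs 8)
  one <- new_superpixel_map(matrix(0L, 4, 5))
  expect_true(all(unclass(oracle_select(one, truth)) == 1L))
  # exact tie 2-2 inside a segment resolves to the smaller id
  t2 <- label_map(matrix(c(1L, 1L, 2L, 2L), 2, 2), pal)
  expect_true(all(unclass(oracle_select(new_superpixel_map(matrix(0L, 2, 2)),
                                        t2)) == 1L))
  # segments aligned with truth reproduce it exactly
  aligned <- new_superpixel_map(matrix(c(rep(0L, 12), rep(1L, 8)), 4, 5))
  expect_identical(unclass(oracle_select(aligned, truth)), unclass(truth))
  expect_error(oracle_select(one, t2), "differ")
})

test_that("oracle selection is the accuracy-optimal constant-per-segment rule", {
  # exhaustive check on a 3-segment toy: no assignment beats the majority
  pal <- default_palette()
  set.seed(31)
  truth <- label_map(matrix(sample(1:3, 36, replace = TRUE), 6, 6), pal)
  seg <- new_superpixel_map(matrix(rep(0:2, each = 12), 6, 6))
  best <- oracle_select(seg, truth)
  acc <- function(m) mean(unclass(m) == unclass(truth))
  for (a1 in 1:3) for (a2 in 1:3) for (a3 in 1:3) {
    cand <- matrix(c(a1, a2, a3)[unclass(seg) + 1L], 6, 6)
    expect_lte(acc(label_map(cand, pal)), acc(best))
  }
  # and it never loses to the global-majority assignment
  glob <- as.integer(names(which.max(table(unclass(truth)))))
  expect_gte(acc(best), acc(label_map(matrix(glob, 6, 6), pal)))
})

test_that("aligned proposals achieve perfect metrics on noise-free scenes", {
  sc <- generate_scene(scene_params(height = 64, width = 64, seed = 13,
                                    noise_sd = 0, illumination = 0))
  met <- achievable_metrics(sc, "felzenszwalb",
                            felz_params(scale_k = 0.01, sigma = 0,
                                        min_size = 1))
  present <- met$class %in%
    attr(sc$truth, "palette")$name[attr(sc$truth, "palette")$id %in%
                                     unique(as.vector(unclass(sc$truth)))]
  expect_true(all(met$fscore[present] == 1))
})

test_that("finer proposals dominate coarser ones end to end", {
  sc <- generate_scene(scene_params(seed = 7))
  f400 <- achievable_metrics(sc, "slic", slic_params(n_segments = 400))
  f4 <- achievable_metrics(sc, "slic", slic_params(n_segments = 4))
  present <- which(table(factor(unclass(sc$truth), levels = 1:5)) > 0)
  expect_true(all(f400$fscore[present] > f4$fscore[present]))
  # single segment: majority class scores, minority classes zero
  f1 <- achievable_metrics(sc, "slic", slic_params(n_segments = 1))
  expect_gt(max(f1$fscore), 0)
  expect_true(any(f1$fscore[present] == 0))
})
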