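# Synthetic scenes and width decomposition.

test_that("scene_params validates its invariants", {
  expect_error(scene_params(image_height = 16), "at least 32")
  expect_error(scene_params(thin_width_range = c(3, 2)), "degenerate")
  expect_error(scene_params(thin_width_range = c(1, 4),
                            thick_width_range = c(3, 8)), "below")
})

test_that("empty scene and determinism contracts hold", {
  p0 <- scene_params(64, 64, n_trees = 0, seed = 3)
  s0 <- generate_scene(p0)
  expect_equal(sum(s0$gt), 0)
  expect_equal(sum(s0$thin) + sum(s0$thick), 0)
  p <- scene_params(64, 64, n_trees = 2, seed = 7)
  expect_identical(generate_scene(p), generate_scene(p))
})

test_that("generated scenes have plausible foreground and both calibres", {
  s <- generate_scene(scene_params(64, 64, n_trees = 2, seed = 7))
  frac <- mean(s$gt)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.40)
  # both width regimes present when n_trees >= 1 and branch_depth >= 2
  for (sd in 1:5) {
    s <- generate_scene(scene_params(64, 64, n_trees = 1, branch_depth = 2,
                                     seed = sd))
    expect_gt(sum(s$thin), 0, label = paste("thin, seed", sd))
    expect_gt(sum(s$thick), 0, label = paste("thick, seed", sd))
  }
})

test_that("vessel pixels are brighter than local background before noise", {
  p <- scene_params(64, 64, n_trees = 2, seed = 2, vessel_contrast = 0.6,
                    background_noise_sd = 0)
  s <- generate_scene(p)
  expect_gt(mean(s$image[s$gt == 1]) - mean(s$image[s$gt == 0]),
            p$vessel_contrast / 2)
})

test_that("decompose_by_width handles the degenerate fixtures", {
  z <- matrix(0, 40, 40)
  d <- decompose_by_width(z, 2)
  expect_equal(sum(d$thin) + sum(d$thick), 0)
  # 1-pixel straight line -> all thin at threshold 2
  line <- matrix(0, 40, 40); line[20, 5:35] <- 1
  d <- decompose_by_width(line, 2)
  expect_equal(d$thin, line)
  expect_equal(sum(d$thick), 0)
  expect_error(decompose_by_width(matrix(0.5, 4, 4)), "binary")
  expect_error(decompose_by_width(z, 0), "positive")
})

test_that("a radius-5 disk is thick, against a brute-force distance oracle", {
  disk <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    if ((i - 20)^2 + (j - 20)^2 <= 25) disk[i, j] <- 1
  }
  d <- decompose_by_width(disk, 2)
  expect_equal(d$thick, disk)
  expect_equal(sum(d$thin), 0)
  # brute-force oracle for the distance transform used inside
  bg <- which(disk == 0, arr.ind = TRUE)
  fg <- which(disk == 1, arr.ind = TRUE)
  brute <- apply(fg, 1, function(px) {
    min((bg[, 1] - px[1])^2 + (bg[, 2] - px[2])^2)
  })
  edt <- distance_transform_sq(disk == 0)
  expect_equal(edt[disk == 1], brute, tolerance = 1e-12)
})

test_that("partition and monotonicity properties hold on generated scenes", {
  for (sd in c(3, 8, 21)) {
    s <- generate_scene(scene_params(64, 64, n_trees = 2, seed = sd))
    prev_thin <- matrix(0, 64, 64)
    for (thr in c(1, 2, 4, 8)) {
      d <- decompose_by_width(s$gt, thr)
      expect_equal(d$thin + d$thick, s$gt)        # exact partition
      expect_equal(sum(d$thin * d$thick), 0)      # empty intersection
      expect_true(all(d$thin >= prev_thin))       # monotone in threshold
      prev_thin <- d$thin
    }
  }
})

test_that("make_dataset writes deterministic, disjoint splits", {
  p <- scene_params(48, 48, n_trees = 1, branch_depth = 2, seed = 3)
  d1 <- tempfile(); d2 <- tempfile()
  make_dataset(d1, 2, 1, 1, p)
  make_dataset(d2, 2, 1, 1, p)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in setdiff(f1, "manifest.yaml")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  # 16 triplets -> 16 files per folder
  d3 <- tempfile()
  make_dataset(d3, 10, 2, 4, p)
  n_img <- length(list.files(d3, pattern = "png$", recursive = TRUE))
  expect_equal(n_img, 16 * 4)
  # empty dataset
  d4 <- tempfile()
  ds <- make_dataset(d4, 0, 0, 0, p)
  expect_equal(sum(lengths(ds$splits)), 0)
  # splits are distinct scenes
  ds3 <- load_dataset(d3)
  expect_false(identical(ds3$splits$train[[1]]$gt, ds3$splits$val[[1]]$gt))
})

test_that("skeletonize keeps a non-empty skeleton on non-empty masks", {
  for (sd in 1:4) {
    s <- generate_scene(scene_params(64, 64, n_trees = 1, seed = sd))
    sk <- skeletonize(s$gt)
    expect_gt(sum(sk), 0)
    expect_true(all(sk <= s$gt))  # skeleton is a subset of the mask
  }
})
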