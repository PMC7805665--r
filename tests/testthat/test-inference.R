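test_that("Gaussian importance weights: centre 1, sigma patch/8, symmetric", {
  w <- gaussian_weights(c(17, 17, 9))
  expect_equal(w[9, 9, 5], 1)            # exact centre of an odd patch
  expect_equal(max(w), 1)
  # one sigma from centre along one axis: exp(-1/2) of the centre value
  sigma <- 17 / 8
  off <- w[9 + round(sigma), 9, 5]
  expected <- exp(-round(sigma)^2 / (2 * sigma^2))
  expect_equal(off, expected, tolerance = 1e-10)
  # mirror symmetry along every axis
  expect_equal(w, w[17:1, , ], tolerance = 1e-12)
  expect_equal(w, w[, 17:1, ], tolerance = 1e-12)
  expect_equal(w, w[, , 9:1], tolerance = 1e-12)
  expect_true(all(w >= 1e-6))
})

test_that("tile positions stride by half the patch and cover everything", {
  # 1-d view: length 256, patch 128 -> starts {0, 64, 128} (0-based)
  tp <- tile_positions(c(256, 128, 128), c(128, 128, 128))
  expect_setequal(unique(tp[, 1]) - 1L, c(0L, 64L, 128L))
  expect_identical(nrow(tile_positions(c(32, 32, 32), c(32, 32, 32))), 1L)
  # coverage oracle over random geometries
  set.seed(81)
  for (rep in 1:50) {
    patch <- sample(seq(4, 16, 2), 3, replace = TRUE)
    shape <- patch + sample(0:20, 3, replace = TRUE)
    tp <- tile_positions(shape, patch)
    covered <- array(FALSE, shape)
    for (r in seq_len(nrow(tp))) {
      cr <- tp[r, ]
      covered[cr[1]:(cr[1] + patch[1] - 1), cr[2]:(cr[2] + patch[2] - 1),
              cr[3]:(cr[3] + patch[3] - 1)] <- TRUE
    }
    expect_true(all(covered))
  }
  expect_error(tile_positions(c(16, 16, 16), c(32, 32, 32)), "smaller than patch")
})

test_that("stitching a constant-output network reproduces the constant", {
  net <- constant_network(c(0.2, 0.3, 0.5))
  set.seed(82)
  for (rep in 1:5) {
    shape <- c(8, 8, 8) + sample(0:10, 3, replace = TRUE)
    plan <- make_plan("t", "full", c(8, 8, 8), c(1, 1, 1), 1)
    sv <- predict_volume(net, ct_volume(rand_array(shape)), plan, tta = FALSE)
    for (c in 1:3)
      expect_equal(max(abs(sv$probs[, , , c] - c(0.2, 0.3, 0.5)[c])), 0,
                   tolerance = 1e-9)
  }
})

test_that("mirror TTA equals plain prediction for an equivariant network", {
  net <- constant_network(c(0.6, 0.3, 0.1))
  plan <- make_plan("t", "full", c(8, 8, 8), c(1, 1, 1), 1)
  vol <- ct_volume(rand_array(c(12, 10, 8), seed = 83))
  a <- predict_volume(net, vol, plan, tta = TRUE)
  b <- predict_volume(net, vol, plan, tta = FALSE)
  expect_equal(a$probs, b$probs, tolerance = 1e-12)
})

test_that("stitched probabilities stay on the simplex for a real network", {
  net <- small_net()
  plan <- make_plan("t", "full", c(8, 8, 4), c(2, 2, 1), 1)
  sv <- predict_volume(net, ct_volume(rand_array(c(12, 12, 6), seed = 84)), plan,
                       tta = TRUE)
  sums <- apply(sv$probs, 1:3, sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-5)
  expect_identical(dim(sv$probs), c(12L, 12L, 6L, 3L))
})

test_that("two-tile weighted average matches hand arithmetic", {
  # volume 12x8x8 with patch 8x8x8 -> two tiles at x-corners 1 and 5; feed
  # hand-set constant outputs per tile and compare every voxel against the
  # scalar formula sum(w p)/sum(w)
  patch <- c(8L, 8L, 8L)
  p_tiles <- list(c(0.9, 0.1), c(0.2, 0.8))
  # the volume stores its own x-coordinate, so the stub can tell which
  # tile it was handed (corner x = 1 vs 5)
  vol <- array(rep(1:12, 8 * 8), c(12, 8, 8))
  stub <- function(patcharr) {
    p <- if (patcharr[1, 1, 1] < 2) p_tiles[[1]] else p_tiles[[2]]
    array(rep(p, each = prod(patch)), c(patch, 2))
  }
  plan <- make_plan("t", "full", patch, c(1, 1, 1), 1)
  sv <- predict_volume(NULL, ct_volume(vol), plan, patch_fun = stub)
  w <- gaussian_weights(patch)
  num <- den <- array(0, c(12, 8, 8))
  for (t in 1:2) {
    idx <- (if (t == 1) 1:8 else 5:12)
    num[idx, , ] <- num[idx, , ] + w * p_tiles[[t]][1]
    den[idx, , ] <- den[idx, , ] + w
  }
  expect_equal(sv$probs[, , , 1], num / den, tolerance = 1e-12)
  expect_equal(sv$probs[, , , 2], 1 - num / den, tolerance = 1e-10)
})

test_that("cross-resolution assembly averages softmax maps then argmaxes", {
  # one voxel: full (0.6, 0.4), low (0.1, 0.9) -> mean (0.35, 0.65) -> class 2
  full <- structure(list(probs = array(c(0.6, 0.4), c(1, 1, 1, 2)),
                         spacing = c(1, 1, 1), affine = NULL), class = "softmax_volume")
  low <- structure(list(probs = array(c(0.1, 0.9), c(1, 1, 1, 2)),
                        spacing = c(2, 2, 2), affine = NULL), class = "softmax_volume")
  lab <- assemble_predictions(full, low)
  expect_identical(lab$labels[1, 1, 1], 1L)  # class index 1 = second class
  # identical inputs: argmax of either
  same <- assemble_predictions(full, full)
  expect_identical(same$labels[1, 1, 1], 0L)
  # simplex preserved through resampling + averaging
  set.seed(85)
  fr <- structure(list(probs = random_softmax(c(8, 8, 4)), spacing = c(1, 1, 1),
                       affine = NULL), class = "softmax_volume")
  lr <- structure(list(probs = random_softmax(c(4, 4, 2)), spacing = c(2, 2, 2),
                       affine = NULL), class = "softmax_volume")
  avg <- gatedseg:::cpp_resize_fwd(lr$probs, c(8L, 8L, 4L))
  expect_identical(dim(avg), c(8L, 8L, 4L, 3L))
  out <- assemble_predictions(fr, lr)
  expect_true(all(out$labels %in% 0:2))
})

test_that("argmax ties break toward the lowest class index", {
  sv <- structure(list(probs = array(c(0.4, 0.4, 0.2), c(1, 1, 1, 3)),
                       spacing = c(1, 1, 1), affine = NULL), class = "softmax_volume")
  expect_identical(predict_labels(sv)$labels[1, 1, 1], 0L)
})

test_that("activation-map export writes bounded attention maps per gate", {
  dir <- withr::local_tempdir()
  net <- small_net()
  plan <- make_plan("t", "full", c(8, 8, 4), c(2, 2, 1), 1)
  vol <- ct_volume(rand_array(c(10, 10, 4), seed = 86))
  maps <- export_activation_maps(net, vol, plan, dir)
  ag_maps <- maps[grep("^attention_", names(maps))]
  expect_length(ag_maps, 2)  # ag_levels = 2
  for (m in ag_maps) {
    expect_true(all(m >= 0 & m <= 1))
    expect_identical(dim(m)[1:3], c(10L, 10L, 4L))
  }
  expect_length(grep("^dsv_level", names(maps)), 2)
  expect_gt(length(list.files(dir, pattern = "nii.gz$")), 0)
  # a gate-free, head-free network exports nothing, with a warning
  plain <- constant_network(c(0.5, 0.3, 0.2))
  plan2 <- make_plan("t", "full", c(8, 8, 8), c(1, 1, 1), 1)
  expect_warning(empty <- export_activation_maps(plain, ct_volume(rand_array(c(8, 8, 8))),
                                                 plan2, dir), "nothing to export")
  expect_length(empty, 0)
})
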