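sparse_case <- function(seed = 61) {
  cs <- shared_phantoms(1)[[1]]
  list(image = cs$image$data, mask = cs$mask$labels, id = "p1")
}

test_that("forced-foreground patches contain foreground and centre on it", {
  cs <- sparse_case()
  set.seed(1)
  for (rep in 1:10) {
    pp <- sample_patch(cs, c(32, 32, 32), force_foreground = TRUE)
    expect_true(any(pp$labels > 0L))
    expect_identical(dim(pp$image), c(32L, 32L, 32L))
  }
})

test_that("small volumes are zero-padded symmetrically", {
  cs <- list(image = rand_array(c(16, 16, 16), seed = 2) + 5,
             mask = array(1L, c(16, 16, 16)))
  set.seed(3)
  pp <- sample_patch(cs, c(32, 32, 32))
  expect_identical(dim(pp$image), c(32L, 32L, 32L))
  # original content sits centred; the border ring is the zero fill
  expect_true(all(pp$image[1:8, , ] == 0))
  expect_true(all(pp$labels[1:8, , ] == 0L))
  expect_equal(pp$image[9:24, 9:24, 9:24], cs$image)
})

test_that("sampling is deterministic under a fixed seed", {
  cs <- sparse_case()
  p1 <- withr::with_seed(7, sample_patch(cs, c(24, 24, 24), force_foreground = TRUE))
  p2 <- withr::with_seed(7, sample_patch(cs, c(24, 24, 24), force_foreground = TRUE))
  expect_identical(p1, p2)
})

test_that("all-background cases fall back to random sampling with a warning", {
  cs <- list(image = rand_array(c(40, 40, 40), seed = 4),
             mask = array(0L, c(40, 40, 40)))
  set.seed(5)
  expect_warning(pp <- sample_patch(cs, c(32, 32, 32), force_foreground = TRUE),
                 "no foreground")
  expect_identical(dim(pp$labels), c(32L, 32L, 32L))
  # batches over an all-background dataset still work
  set.seed(6)
  expect_warning(b <- sample_batch(list(cs), 2, c(32, 32, 32)), "no foreground")
  expect_length(b, 2)
})

test_that("every batch honours the foreground guarantee", {
  cases <- lapply(shared_phantoms(3), function(cs)
    list(image = cs$image$data, mask = cs$mask$labels))
  set.seed(8)
  for (rep in 1:50) {
    b <- sample_batch(cases, 2, c(32, 32, 32))
    expect_true(any(vapply(b, function(p) any(p$labels > 0L), logical(1))))
  }
  # batch_size 1: the single patch is the forced one
  set.seed(9)
  for (rep in 1:10) {
    b <- sample_batch(cases, 1, c(32, 32, 32))
    expect_true(any(b[[1]]$labels > 0L))
  }
  expect_error(sample_batch(list(), 2, c(8, 8, 8)), "empty")
})

test_that("mirroring twice restores the patch exactly", {
  cfg <- augment_config(rotation_p = 0, scale_p = 0, elastic_p = 0, gamma_p = 0,
                        mirror_p = 1, mirror_axes = 1L)
  pp <- list(image = rand_array(c(8, 8, 8), seed = 10),
             labels = array(sample(0:2, 512, TRUE), c(8, 8, 8)))
  once <- withr::with_seed(1, augment_patch(pp, cfg))
  twice <- withr::with_seed(1, augment_patch(once, cfg))
  expect_identical(twice$image, pp$image)
  expect_identical(twice$labels, pp$labels)
})

test_that("identity configuration leaves the pair unchanged", {
  cfg <- augment_config(rotation_p = 0, scale_p = 0, elastic_p = 0, gamma_p = 0,
                        mirror_p = 0)
  pp <- list(image = rand_array(c(8, 8, 8), seed = 11),
             labels = array(sample(0:2, 512, TRUE), c(8, 8, 8)))
  out <- withr::with_seed(2, augment_patch(pp, cfg))
  expect_identical(out$image, pp$image)
  expect_identical(out$labels, pp$labels)
})

test_that("spatial and intensity transforms preserve shape and label set", {
  cfg <- augment_config(rotation_p = 1, scale_p = 1, elastic_p = 1, gamma_p = 1,
                        mirror_p = 0.5)
  cs <- sparse_case()
  set.seed(12)
  for (rep in 1:5) {
    pp <- sample_patch(cs, c(24, 24, 24), force_foreground = TRUE)
    out <- augment_patch(pp, cfg)
    expect_identical(dim(out$image), dim(pp$image))
    expect_identical(dim(out$labels), dim(pp$labels))
    expect_true(all(out$labels %in% 0:2))
  }
})

test_that("gamma = 1 with identity spatial transform changes nothing", {
  cfg <- augment_config(rotation_p = 0, scale_p = 0, elastic_p = 0,
                        gamma_p = 1, gamma_range = c(1, 1), mirror_p = 0)
  pp <- list(image = rand_array(c(6, 6, 6), seed = 13),
             labels = array(0L, c(6, 6, 6)))
  out <- withr::with_seed(3, augment_patch(pp, cfg))
  expect_equal(out$image, pp$image, tolerance = 1e-12)
})
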