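make_case <- function(intens, labels, spacing = c(1, 1, 1)) {
  list(image = ct_volume(intens, spacing = spacing),
       mask = ct_labelmask(labels, spacing = spacing))
}

test_that("foreground statistics match direct computation", {
  # 1000 voxels at 10 and 1000 at 20 inside the mask -> mean 15, sd 5
  dm <- c(20, 10, 10)
  intens <- array(999, dm)
  labels <- array(0L, dm)
  labels[1:10, , ] <- 1L
  intens[1:5, , ] <- 10
  intens[6:10, , ] <- 20
  fp <- compute_fingerprint(list(make_case(intens, labels)))
  expect_equal(fp$fg_mean, 15)
  expect_equal(fp$fg_std, 5)
  expect_true(fp$fg_p005 <= fp$fg_p995)
})

test_that("percentiles agree with a full-sort oracle", {
  set.seed(31)
  for (rep in 1:10) {
    dm <- c(12, 12, 6)
    intens <- rand_array(dm)
    labels <- array(rbinom(prod(dm), 1, 0.4), dm)
    if (sum(labels) < 10) next
    fp <- compute_fingerprint(list(make_case(intens, labels)))
    fg <- sort(intens[labels > 0])
    # linear interpolation between order statistics (type-7 definition)
    qo <- function(p) {
      h <- (length(fg) - 1) * p
      lo <- floor(h)
      fg[lo + 1] + (h - lo) * (fg[min(lo + 2, length(fg))] - fg[lo + 1])
    }
    expect_equal(fp$fg_p005, qo(0.005), tolerance = 1e-10)
    expect_equal(fp$fg_p995, qo(0.995), tolerance = 1e-10)
  }
})

test_that("median spacing/shape pool across cases and zero foreground errors", {
  c1 <- make_case(rand_array(c(10, 10, 10)), array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
  c2 <- make_case(rand_array(c(10, 10, 10)), array(1L, c(10, 10, 10)), spacing = c(2, 2, 2))
  c3 <- make_case(rand_array(c(10, 10, 10)), array(1L, c(10, 10, 10)), spacing = c(3, 3, 3))
  fp <- compute_fingerprint(list(c1, c2, c3))
  expect_equal(fp$median_spacing, c(2, 2, 2))
  expect_error(compute_fingerprint(list(make_case(rand_array(c(6, 6, 6)), array(0L, c(6, 6, 6))))),
               "no foreground")
})

test_that("normalization clips then z-scores; degenerate sd errors", {
  dm <- c(8, 8, 8)
  intens <- rand_array(dm, seed = 4) * 50 + 100
  labels <- array(1L, dm)
  fp <- compute_fingerprint(list(make_case(intens, labels)))
  nv <- normalize_volume(ct_volume(intens), fp)
  # anything at/above the upper clip maps to the same value
  hi <- (fp$fg_p995 - fp$fg_mean) / fp$fg_std
  probe <- normalize_volume(ct_volume(array(c(fp$fg_p995, fp$fg_p995 + 500, -1e6, fp$fg_p005), c(1, 1, 4))), fp)
  expect_equal(probe$data[1, 1, 1], hi)
  expect_equal(probe$data[1, 1, 2], hi)
  expect_equal(probe$data[1, 1, 3], probe$data[1, 1, 4])
  # pooled foreground after transform: mean 0, sd 1 (clipping touches <=1%)
  fg <- nv$data[labels > 0]
  expect_lt(abs(mean(fg)), 0.05)
  expect_lt(abs(sqrt(mean((fg - mean(fg))^2)) - 1), 0.05)
  bad <- fp; bad$fg_std <- 0
  expect_error(normalize_volume(ct_volume(intens), bad), "standard deviation")
})

test_that("low-resolution spacing rule picks the minimal halving count", {
  fp <- structure(list(median_spacing = c(0.8, 0.8, 3), median_shape = c(511, 511, 136)),
                  class = "dataset_fingerprint")
  res <- lowres_spacing(fp, c(128, 128, 128))
  expect_identical(res$k, 1L)  # 35.5M >= 8.39M; one halving -> 4.43M < 8.39M
  expect_equal(res$target_spacing, c(1.6, 1.6, 6))
  # already small -> k = 0, spacing unchanged
  fp$median_shape <- c(100, 100, 50)
  expect_identical(lowres_spacing(fp, c(128, 128, 128))$k, 0L)
  # minimal k property vs exhaustive search, random fingerprints
  set.seed(99)
  for (rep in 1:20) {
    fp$median_shape <- round(runif(3, 60, 700))
    patch <- round(runif(3, 32, 160))
    res <- lowres_spacing(fp, patch)
    ks <- 0:10
    ok <- vapply(ks, function(k) prod(fp$median_shape / 2^k) < 4 * prod(patch), logical(1))
    expect_identical(res$k, as.integer(min(ks[ok])))
  }
})

test_that("task presets reproduce the published configurations", {
  k <- plan_for_task("kidney", "full")
  expect_identical(k$patch_size, c(160L, 160L, 48L))
  expect_identical(k$levels_per_axis, c(5L, 5L, 3L))
  expect_identical(k$batch_size, 2L)
  kl <- plan_for_task("kidney", "low")
  expect_identical(kl$patch_size, c(128L, 128L, 80L))
  expect_identical(kl$levels_per_axis, c(5L, 5L, 4L))
  p <- plan_for_task("pancreas", "low")
  expect_identical(p$patch_size, c(64L, 128L, 128L))
  expect_identical(p$levels_per_axis, c(3L, 5L, 5L))
  pf <- plan_for_task("pancreas", "full")
  expect_identical(pf$patch_size, c(40L, 192L, 160L))
  l <- plan_for_task("liver", "full")
  expect_identical(l$patch_size, c(96L, 128L, 128L))
  expect_identical(l$levels_per_axis, c(5L, 5L, 5L))
  expect_error(plan_for_task("spleen", "full"), "unknown task preset")
})

test_that("plan validation rejects indivisible patches", {
  expect_error(make_plan("t", "full", c(100, 128, 128), c(5, 5, 5), 2), "not divisible")
  expect_error(make_plan("t", "full", c(128, 128, 128), c(5, 5, 5), 0), "batch_size")
})
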