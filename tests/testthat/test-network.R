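test_that("feature schedule doubles with a cap at every level", {
  spec <- network_spec(variant = "vnet", base_features = 30,
                       levels_per_axis = c(5, 5, 5), feature_cap = 320)
  feats <- vapply(0:5, function(l) gatedseg:::spec_features(spec, l), integer(1))
  expect_identical(feats, c(30L, 60L, 120L, 240L, 320L, 320L))
})

test_that("per-axis level budgets stop downsampling on exhausted axes", {
  spec <- network_spec(variant = "vnet", base_features = 2,
                       levels_per_axis = c(3, 3, 1), dropout_p = 0,
                       ag_levels = 0, dsv_levels = 0)
  net <- build_network(spec, seed = 1)
  p <- forward_pass(net, rand_array(c(16, 16, 4), seed = 1))
  expect_identical(dim(p), c(16L, 16L, 4L, 3L))
  # axis 3 is downsampled only once: stride factors are (2,2,2),(2,2,1),(2,2,1)
  expect_identical(gatedseg:::spec_stride(spec, 1L), c(2L, 2L, 2L))
  expect_identical(gatedseg:::spec_stride(spec, 2L), c(2L, 2L, 1L))
  expect_identical(gatedseg:::spec_stride(spec, 3L), c(2L, 2L, 1L))
})

test_that("forward output is a voxel-wise softmax over classes", {
  net <- small_net()
  p1 <- forward_pass(net, rand_array(c(8, 8, 4), seed = 11))
  set.seed(42)  # eval mode must ignore the RNG
  p2 <- forward_pass(net, rand_array(c(8, 8, 4), seed = 11))
  expect_identical(p1, p2)  # deterministic in eval mode
  sums <- apply(p1, 1:3, sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-5)
  expect_true(all(p1 >= 0))
})

test_that("zero-weight head yields the uniform softmax", {
  net <- constant_network(c(1, 1, 1) / 3)
  p <- forward_pass(net, rand_array(c(8, 8, 8), seed = 2))
  expect_equal(max(abs(p - 1 / 3)), 0, tolerance = 1e-12)
})

test_that("invalid input shapes are rejected", {
  net <- small_net()
  expect_error(forward_pass(net, rand_array(c(7, 8, 4))), "not divisible")
})

test_that("parameter counting is exact and patch-size independent", {
  # single 1x1x1 conv, 4 -> 3 channels with bias: 4*3 + 3 = 15
  w <- matrix(rnorm(12), 4, 3)
  expect_identical(length(w) + 3L, 15L)
  net <- small_net()
  expect_identical(count_parameters(net),
                   sum(vapply(net$params, length, integer(1))))
  # fully convolutional: the count never references a patch size
  n1 <- build_network(small_spec(), patch_size = c(8, 8, 4), seed = 1)
  n2 <- build_network(small_spec(), patch_size = c(16, 16, 8), seed = 1)
  expect_identical(count_parameters(n1), count_parameters(n2))
})

test_that("V-Net has more parameters than U-Net for the same spec", {
  nv <- build_network(small_spec("vnet"), seed = 1)
  nu <- build_network(small_spec("unet"), seed = 1)
  expect_gt(count_parameters(nv), count_parameters(nu))
})

test_that("U-Net forward preserves shape and the softmax simplex", {
  net <- small_net("unet")
  p <- forward_pass(net, rand_array(c(8, 8, 4), seed = 3))
  expect_identical(dim(p), c(8L, 8L, 4L, 3L))
  expect_equal(max(abs(apply(p, 1:3, sum) - 1)), 0, tolerance = 1e-5)
})

test_that("gradients reach every parameter after one backward pass", {
  for (variant in c("vnet", "unet")) for (ag in c(TRUE, FALSE)) {
    net <- build_network(small_spec(variant, ag), seed = 3)
    set.seed(5)
    patch <- rand_array(c(8, 8, 4))
    labels <- array(sample(0:2, 8 * 8 * 4, TRUE), c(8, 8, 4))
    g <- gatedseg:::net_graph(net, patch, train = TRUE)
    lg <- gatedseg:::loss_and_grad(gatedseg:::ag_value(g$tape, g$logits), labels, 3)
    gatedseg:::ag_backward(g$tape, g$logits, lg$grad_logits)
    for (nm in ls(g$pids)) {
      gr <- gatedseg:::ag_grad(g$tape, g$pids[[nm]])
      expect_false(is.null(gr), info = paste(variant, ag, nm))
    }
    expect_identical(length(ls(g$pids)), length(net$params))
  }
})

test_that("analytic gradients match directional finite differences", {
  # one random direction over all parameters; fp32 convolution kernels
  # limit the attainable fd accuracy, so compare at matched step/tolerance
  net <- build_network(small_spec("vnet", ag = TRUE), seed = 9)
  set.seed(21)
  patch <- rand_array(c(8, 8, 4))
  labels <- array(sample(0:2, 8 * 8 * 4, TRUE), c(8, 8, 4))
  loss_of <- function(net) {
    g <- gatedseg:::net_graph(net, patch, train = FALSE)
    gatedseg:::loss_and_grad(gatedseg:::ag_value(g$tape, g$logits), labels, 3)$total
  }
  g <- gatedseg:::net_graph(net, patch, train = FALSE)
  lg <- gatedseg:::loss_and_grad(gatedseg:::ag_value(g$tape, g$logits), labels, 3)
  gatedseg:::ag_backward(g$tape, g$logits, lg$grad_logits)
  dirs <- lapply(net$params, function(p)
    array(rnorm(length(p)), if (is.null(dim(p))) length(p) else dim(p)))
  names(dirs) <- names(net$params)
  dd_analytic <- sum(vapply(names(net$params), function(nm) {
    gr <- gatedseg:::ag_grad(g$tape, g$pids[[nm]])
    sum(gr * dirs[[nm]])
  }, numeric(1)))
  shift <- function(s) {
    np <- net
    for (nm in names(np$params)) np$params[[nm]] <- np$params[[nm]] + s * dirs[[nm]]
    np
  }
  fd <- function(h) (loss_of(shift(h)) - loss_of(shift(-h))) / (2 * h)
  # Richardson extrapolation tames the curvature of the strongly
  # non-linear loss; the single-precision convolution path bounds the
  # attainable agreement
  d1 <- fd(2e-4); d2 <- fd(1e-4)
  dd_fd <- (4 * d2 - d1) / 3
  expect_lt(abs(dd_analytic - dd_fd), max(0.03 * abs(dd_fd), 0.01))
})

test_that("spec validation enforces the level and gating constraints", {
  expect_error(network_spec(levels_per_axis = c(6, 5, 5)), "0..5")
  expect_error(network_spec(ag_levels = 3, dsv_levels = 2), "ag_levels")
  expect_error(network_spec(levels_per_axis = c(3, 3, 3), dsv_levels = 4), "dsv_levels")
})
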