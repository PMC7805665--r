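# Exact finite-difference checks of the individual tensor operations.
# These run in double precision (only the 3x3x3 convolution GEMMs are
# single precision internally, and get a matched tolerance).

op_grad_check <- function(fwd, bwd_inputs, h = 1e-6, tol = 1e-6) {
  # fwd: function(inputs) -> array; bwd_inputs: list of input arrays with
  # attribute "grad" holding the analytic gradient for a random seed gy
  for (nm in setdiff(names(bwd_inputs), ".gy")) {
    x <- bwd_inputs[[nm]]$value
    an <- bwd_inputs[[nm]]$grad
    idxs <- sample(length(x), min(4, length(x)))
    for (ii in idxs) {
      xp <- x; xp[ii] <- xp[ii] + h
      xm <- x; xm[ii] <- xm[ii] - h
      fd <- (sum(fwd(nm, xp) * bwd_inputs$.gy) - sum(fwd(nm, xm) * bwd_inputs$.gy)) / (2 * h)
      expect_equal(an[ii], fd, tolerance = tol,
                   label = sprintf("%s[%d] analytic", nm, ii))
    }
  }
}

test_that("strided and transposed block convolutions backpropagate exactly", {
  set.seed(301)
  x <- rand_array(c(4, 4, 2, 3))
  w <- rand_array(c(2, 2, 1, 3, 5))   # kernel (2,2,1), 3 -> 5 channels
  b <- rnorm(5)
  f <- c(2L, 2L, 1L)
  gy <- rand_array(c(2, 2, 2, 5))
  g <- gatedseg:::cpp_blockdown_bwd(x, w, gy, f)
  op_grad_check(
    fwd = function(nm, v) switch(nm,
      x = gatedseg:::cpp_blockdown_fwd(v, w, b, f),
      w = gatedseg:::cpp_blockdown_fwd(x, v, b, f)),
    bwd_inputs = list(x = list(value = x, grad = g$gx),
                      w = list(value = w, grad = g$gw), .gy = gy))
  # transposed: weight dim (f, Cout, Cin)
  wu <- rand_array(c(2, 2, 1, 5, 3))
  gyu <- rand_array(c(8, 8, 2, 5))
  gu <- gatedseg:::cpp_blockup_bwd(x, wu, gyu, f)
  op_grad_check(
    fwd = function(nm, v) switch(nm,
      x = gatedseg:::cpp_blockup_fwd(v, wu, numeric(5), f),
      w = gatedseg:::cpp_blockup_fwd(x, v, numeric(5), f)),
    bwd_inputs = list(x = list(value = x, grad = gu$gx),
                      w = list(value = wu, grad = gu$gw), .gy = gyu))
})

test_that("trilinear resize backward is the exact adjoint of forward", {
  set.seed(302)
  x <- rand_array(c(3, 4, 2, 2))
  out_dims <- c(6L, 8L, 4L)
  gy <- rand_array(c(out_dims, 2))
  gx <- gatedseg:::cpp_resize_bwd(gy, as.integer(dim(x)))
  # adjoint identity: <resize(x), gy> == <x, resize^T(gy)> for all x
  expect_equal(sum(gatedseg:::cpp_resize_fwd(x, out_dims) * gy),
               sum(x * gx), tolerance = 1e-10)
  # and against the loop oracle
  expect_equal(gatedseg:::cpp_resize_fwd(x, out_dims), oracle_trilinear(x, out_dims),
               tolerance = 1e-10)
})

test_that("max pooling routes gradients to the argmax voxels", {
  set.seed(303)
  x <- rand_array(c(4, 4, 2, 2))
  f <- c(2L, 2L, 2L)
  fw <- gatedseg:::cpp_maxpool_fwd(x, f)
  gy <- rand_array(c(2, 2, 1, 2))
  gx <- gatedseg:::cpp_maxpool_bwd(fw$argmax, gy, as.integer(dim(x)))
  h <- 1e-6
  for (ii in sample(length(x), 6)) {
    xp <- x; xp[ii] <- xp[ii] + h
    xm <- x; xm[ii] <- xm[ii] - h
    fd <- (sum(gatedseg:::cpp_maxpool_fwd(xp, f)$y * gy) -
           sum(gatedseg:::cpp_maxpool_fwd(xm, f)$y * gy)) / (2 * h)
    expect_equal(gx[ii], fd, tolerance = 1e-5)
  }
})

test_that("3x3x3 convolution matches a direct loop on small instances", {
  set.seed(304)
  x <- rand_array(c(4, 3, 3, 2))
  w <- rand_array(c(3, 3, 3, 2, 2))
  b <- rnorm(2)
  y <- gatedseg:::cpp_conv3_fwd(x, w, b)
  ref <- array(0, c(4, 3, 3, 2))
  for (co in 1:2) for (i in 1:4) for (j in 1:3) for (k in 1:3) {
    s <- b[co]
    for (ci in 1:2) for (a in -1:1) for (b2 in -1:1) for (cc in -1:1) {
      ii <- i + a; jj <- j + b2; kk <- k + cc
      if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 3 && kk >= 1 && kk <= 3)
        s <- s + x[ii, jj, kk, ci] * w[a + 2, b2 + 2, cc + 2, ci, co]
    }
    ref[i, j, k, co] <- s
  }
  expect_equal(y, ref, tolerance = 1e-5)
  # backward against central differences (fp32 kernels: matched step)
  gy <- rand_array(c(4, 3, 3, 2))
  g <- gatedseg:::cpp_conv3_bwd(x, w, gy, TRUE)
  h <- 1e-3
  for (ii in sample(length(w), 4)) {
    wp <- w; wp[ii] <- wp[ii] + h
    wm <- w; wm[ii] <- wm[ii] - h
    fd <- (sum(gatedseg:::cpp_conv3_fwd(x, wp, b) * gy) -
           sum(gatedseg:::cpp_conv3_fwd(x, wm, b) * gy)) / (2 * h)
    expect_equal(g$gw[ii], fd, tolerance = 1e-3)
  }
  for (ii in sample(length(x), 4)) {
    xp <- x; xp[ii] <- xp[ii] + h
    xm <- x; xm[ii] <- xm[ii] - h
    fd <- (sum(gatedseg:::cpp_conv3_fwd(xp, w, b) * gy) -
           sum(gatedseg:::cpp_conv3_fwd(xm, w, b) * gy)) / (2 * h)
    expect_equal(g$gx[ii], fd, tolerance = 1e-3)
  }
})

test_that("instance norm and 1x1x1 conv backward are exact", {
  set.seed(305)
  x <- rand_array(c(4, 4, 2, 3))
  gam <- rnorm(3); bet <- rnorm(3)
  fw <- gatedseg:::cpp_instnorm_fwd(x, gam, bet, 1e-5)
  gy <- rand_array(dim(x))
  bw <- gatedseg:::cpp_instnorm_bwd(x, gam, gy, fw$mu, fw$istd)
  h <- 1e-6
  for (ii in sample(length(x), 5)) {
    xp <- x; xp[ii] <- xp[ii] + h
    xm <- x; xm[ii] <- xm[ii] - h
    fd <- (sum(gatedseg:::cpp_instnorm_fwd(xp, gam, bet, 1e-5)$y * gy) -
           sum(gatedseg:::cpp_instnorm_fwd(xm, gam, bet, 1e-5)$y * gy)) / (2 * h)
    expect_equal(bw$gx[ii], fd, tolerance = 1e-5)
  }
  w1 <- matrix(rnorm(6), 3, 2); b1 <- rnorm(2)
  y <- gatedseg:::cpp_conv1_fwd(x, w1, b1)
  gy1 <- rand_array(dim(y))
  g1 <- gatedseg:::cpp_conv1_bwd(x, w1, gy1)
  for (ii in sample(length(w1), 3)) {
    wp <- w1; wp[ii] <- wp[ii] + h
    wm <- w1; wm[ii] <- wm[ii] - h
    fd <- (sum(gatedseg:::cpp_conv1_fwd(x, wp, b1) * gy1) -
           sum(gatedseg:::cpp_conv1_fwd(x, wm, b1) * gy1)) / (2 * h)
    expect_equal(g1$gw[ii], fd, tolerance = 1e-6)
  }
})

test_that("fused instance-norm + leaky-ReLU equals the op composition exactly", {
  set.seed(306)
  x <- rand_array(c(4, 4, 2, 3))
  gam <- rnorm(3); bet <- rnorm(3)
  fw <- gatedseg:::cpp_in_lrelu_fwd(x, gam, bet, 1e-5, 0.01)
  f2 <- gatedseg:::cpp_instnorm_fwd(x, gam, bet, 1e-5)
  expect_identical(fw$y, gatedseg:::cpp_lrelu_fwd(f2$y, 0.01))
  gy <- rand_array(dim(x))
  bw <- gatedseg:::cpp_in_lrelu_bwd(x, gam, bet, gy, fw$mu, fw$istd, 0.01)
  g2 <- gatedseg:::cpp_lrelu_bwd(f2$y, gy, 0.01)
  b2 <- gatedseg:::cpp_instnorm_bwd(x, gam, g2, f2$mu, f2$istd)
  expect_equal(bw$gx, b2$gx, tolerance = 1e-12)
  expect_equal(bw$dgamma, b2$dgamma, tolerance = 1e-12)
  expect_equal(bw$dbeta, b2$dbeta, tolerance = 1e-12)
})
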