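#' @useDynLib gatedseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal reverse-mode automatic differentiation.
#
# A tape is an environment collecting nodes in creation order.  Each node
# holds a value (an array), the ids of its parents, and a backward closure
# mapping the node's output gradient to a list of parent gradients.
# Backpropagation walks the tape in reverse creation order, which is a
# valid topological order because parents are always created before
# children.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$k <- 0L
  class(tp) <- "ag_tape"
  tp
}

ag_push <- function(tape, value, parents = integer(0), backward = NULL) {
  k <- tape$k + 1L
  if (k > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[k]] <- list(value = value, parents = as.integer(parents),
                          backward = backward, grad = NULL)
  tape$k <- k
  k
}

# NB: force id before touching tape$nodes — the id argument is often a
# call that itself pushes onto the tape (lazy evaluation would otherwise
# read the node list before the push).
ag_value <- function(tape, id) {
  force(id)
  tape$nodes[[id]]$value
}

ag_grad <- function(tape, id) {
  force(id)
  tape$nodes[[id]]$grad
}

# Seed the gradient of `id` and propagate to every reachable node.
ag_backward <- function(tape, id, seed = 1) {
  tape$nodes[[id]]$grad <- seed
  for (i in rev(seq_len(tape$k))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward) || length(nd$parents) == 0L) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (is.null(gs[[j]])) next
      p <- nd$parents[[j]]
      g0 <- tape$nodes[[p]]$grad
      tape$nodes[[p]]$grad <- if (is.null(g0)) gs[[j]] else g0 + gs[[j]]
    }
  }
  invisible(tape)
}

# --- tensor ops ------------------------------------------------------------
# All activations are 4-d arrays dim c(x, y, z, channels).

op_input <- function(tape, x) ag_push(tape, x)

# 3x3x3 "same" convolution; need_gx = FALSE skips the data gradient for
# convolutions applied directly to the network input
op_conv3 <- function(tape, xid, wid, bid, need_gx = TRUE) {
  need_gx <- isTRUE(need_gx)  # force now: the closure below must not capture
                              # a promise referencing a caller loop variable
  x <- ag_value(tape, xid); w <- ag_value(tape, wid); b <- ag_value(tape, bid)
  y <- cpp_conv3_fwd(x, w, b)
  ag_push(tape, y, c(xid, wid, bid), function(gy) {
    g <- cpp_conv3_bwd(x, w, gy, need_gx)
    list(g$gx, g$gw, g$gb)
  })
}

# 1x1x1 convolution (channel mixing); w: Cin x Cout matrix
op_conv1 <- function(tape, xid, wid, bid) {
  x <- ag_value(tape, xid); w <- ag_value(tape, wid); b <- ag_value(tape, bid)
  y <- cpp_conv1_fwd(x, w, b)
  ag_push(tape, y, c(xid, wid, bid), function(gy) {
    g <- cpp_conv1_bwd(x, w, gy)
    list(g$gx, g$gw, g$gb)
  })
}

# strided (kernel == stride == f) convolution, V-Net downsampling
op_blockdown <- function(tape, xid, wid, bid, f) {
  x <- ag_value(tape, xid); w <- ag_value(tape, wid); b <- ag_value(tape, bid)
  f <- as.integer(f)
  y <- cpp_blockdown_fwd(x, w, b, f)
  ag_push(tape, y, c(xid, wid, bid), function(gy) {
    g <- cpp_blockdown_bwd(x, w, gy, f)
    list(g$gx, g$gw, g$gb)
  })
}

# transposed (kernel == stride == f) convolution, V-Net upsampling
op_blockup <- function(tape, xid, wid, bid, f) {
  x <- ag_value(tape, xid); w <- ag_value(tape, wid); b <- ag_value(tape, bid)
  f <- as.integer(f)
  y <- cpp_blockup_fwd(x, w, b, f)
  ag_push(tape, y, c(xid, wid, bid), function(gy) {
    g <- cpp_blockup_bwd(x, w, gy, f)
    list(g$gx, g$gw, g$gb)
  })
}

op_maxpool <- function(tape, xid, f) {
  x <- ag_value(tape, xid)
  f <- as.integer(f)
  fw <- cpp_maxpool_fwd(x, f)
  in_dims <- as.integer(dim(x))
  ag_push(tape, fw$y, xid, function(gy) {
    list(cpp_maxpool_bwd(fw$argmax, gy, in_dims))
  })
}

# trilinear resize to an arbitrary spatial shape (channels preserved)
op_resize <- function(tape, xid, out_shape) {
  x <- ag_value(tape, xid)
  out_shape <- as.integer(out_shape)
  in_dims <- as.integer(dim(x))
  y <- cpp_resize_fwd(x, out_shape)
  ag_push(tape, y, xid, function(gy) list(cpp_resize_bwd(gy, in_dims)))
}

# 1x1x1 convolution with spatial stride f and no bias (attention-gate x path)
op_strided1 <- function(tape, xid, wid, f) {
  x <- ag_value(tape, xid); w <- ag_value(tape, wid)
  dm <- dim(x)
  ix <- seq.int(1L, dm[1], by = f[1])
  iy <- seq.int(1L, dm[2], by = f[2])
  iz <- seq.int(1L, dm[3], by = f[3])
  xs <- x[ix, iy, iz, , drop = FALSE]
  sdm <- dim(xs); n <- prod(sdm[1:3])
  ym <- matrix(xs, n, sdm[4]) %*% w
  y <- array(ym, c(sdm[1:3], ncol(w)))
  ag_push(tape, y, c(xid, wid), function(gy) {
    gym <- matrix(gy, n, ncol(w))
    gxs <- array(gym %*% t(w), sdm)
    gx <- array(0, dm)
    gx[ix, iy, iz, ] <- gxs
    list(gx, crossprod(matrix(xs, n, sdm[4]), gym))
  })
}

op_lrelu <- function(tape, xid, slope) {
  x <- ag_value(tape, xid)
  ag_push(tape, cpp_lrelu_fwd(x, slope), xid,
          function(gy) list(cpp_lrelu_bwd(x, gy, slope)))
}

op_relu <- function(tape, xid) {
  x <- ag_value(tape, xid)
  mask <- (x > 0) * 1
  ag_push(tape, x * mask, xid, function(gy) list(gy * mask))
}

op_sigmoid <- function(tape, xid) {
  x <- ag_value(tape, xid)
  y <- 1 / (1 + exp(-x))
  ag_push(tape, y, xid, function(gy) list(gy * y * (1 - y)))
}

# inverted dropout; identity in eval mode
op_dropout <- function(tape, xid, p, train) {
  if (!train || p <= 0) return(xid)
  fw <- cpp_dropout_fwd(ag_value(tape, xid), p)
  ag_push(tape, fw$y, xid,
          function(gy) list(cpp_dropout_bwd(fw$keep, gy, fw$scale)))
}

# instance normalization: per-channel mean/variance over the spatial grid
# of the (single-sample) activation, with a trainable affine map.
op_instnorm <- function(tape, xid, gid, bid, eps = 1e-5) {
  x <- ag_value(tape, xid)
  gamma <- ag_value(tape, gid); beta <- ag_value(tape, bid)
  fw <- cpp_instnorm_fwd(x, gamma, beta, eps)
  ag_push(tape, fw$y, c(xid, gid, bid), function(gy) {
    g <- cpp_instnorm_bwd(x, gamma, gy, fw$mu, fw$istd)
    list(g$gx, g$dgamma, g$dbeta)
  })
}

op_add <- function(tape, aid, bid) {
  a <- ag_value(tape, aid); b <- ag_value(tape, bid)
  ag_push(tape, a + b, c(aid, bid), function(gy) list(gy, gy))
}

op_add_bias <- function(tape, xid, bid) {
  # bias: one scalar per channel
  x <- ag_value(tape, xid); b <- ag_value(tape, bid)
  dm <- dim(x); n <- prod(dm[1:3])
  y <- array(sweep(matrix(x, n, dm[4]), 2L, b, "+"), dm)
  ag_push(tape, y, c(xid, bid), function(gy) {
    list(gy, colSums(matrix(gy, n, dm[4])))
  })
}

# multiply a C-channel activation by a single-channel map (broadcast)
op_mul_alpha <- function(tape, xid, aid) {
  x <- ag_value(tape, xid); alpha <- ag_value(tape, aid)
  y <- cpp_mul_alpha_fwd(x, alpha)
  ag_push(tape, y, c(xid, aid), function(gy) {
    g <- cpp_mul_alpha_bwd(x, alpha, gy)
    list(g$gx, g$ga)
  })
}

op_concat <- function(tape, aid, bid) {
  a <- ag_value(tape, aid); b <- ag_value(tape, bid)
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  y <- c(a, b)
  dim(y) <- c(da[1:3], da[4] + db[4])
  na <- length(a)
  ag_push(tape, y, c(aid, bid), function(gy) {
    ga <- gy[seq_len(na)]; dim(ga) <- da
    gb <- gy[na + seq_len(length(b))]; dim(gb) <- db
    list(ga, gb)
  })
}


# fused instance norm + leaky ReLU (per conv block tail); one C++ pass
# each way instead of separate ops
op_in_lrelu <- function(tape, xid, gid, bid, slope, eps = 1e-5) {
  x <- ag_value(tape, xid)
  gamma <- ag_value(tape, gid); beta <- ag_value(tape, bid)
  fw <- cpp_in_lrelu_fwd(x, gamma, beta, eps, slope)
  ag_push(tape, fw$y, c(xid, gid, bid), function(gy) {
    g <- cpp_in_lrelu_bwd(x, gamma, beta, gy, fw$mu, fw$istd, slope)
    list(g$gx, g$dgamma, g$dbeta)
  })
}
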