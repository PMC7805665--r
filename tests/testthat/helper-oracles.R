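# Independent scalar-loop oracles used to validate the vectorized /
# compiled implementations.  These deliberately mirror the defining
# formulas voxel by voxel and stay independent of the package internals.

oracle_attention_alpha <- function(x, g, p) {
  # additive attention on the coarse grid: per voxel q = psi' relu(Wx'x +
  # Wg'g + bg) + bpsi, alpha = sigmoid(q); x already at g's grid
  dg <- dim(g)
  alpha <- array(NA_real_, dg[1:3])
  for (i in seq_len(dg[1])) for (j in seq_len(dg[2])) for (k in seq_len(dg[3])) {
    xv <- x[i, j, k, ]
    gv <- g[i, j, k, ]
    h <- pmax(as.vector(t(p$wx) %*% xv + t(p$wg) %*% gv) + p$bg, 0)
    q <- sum(p$psi * h) + p$bpsi
    alpha[i, j, k] <- 1 / (1 + exp(-q))
  }
  alpha
}

oracle_gate <- function(x, alpha) {
  out <- array(NA_real_, dim(x))
  for (i in seq_len(dim(x)[1])) for (j in seq_len(dim(x)[2]))
    for (k in seq_len(dim(x)[3])) for (c in seq_len(dim(x)[4]))
      out[i, j, k, c] <- x[i, j, k, c] * alpha[i, j, k]
  out
}

oracle_dice_loss <- function(u, v, eps = 1e-5) {
  C <- dim(u)[4]
  acc <- 0
  for (c in seq_len(C)) {
    num <- 0; du <- 0; dv <- 0
    for (i in seq_len(dim(u)[1])) for (j in seq_len(dim(u)[2])) for (k in seq_len(dim(u)[3])) {
      num <- num + u[i, j, k, c] * v[i, j, k, c]
      du <- du + u[i, j, k, c]
      dv <- dv + v[i, j, k, c]
    }
    acc <- acc + num / (du + dv + eps)
  }
  -2 / C * acc
}

oracle_ce_loss <- function(u, v, clamp = 1e-7) {
  s <- 0; n <- 0
  for (i in seq_len(dim(u)[1])) for (j in seq_len(dim(u)[2])) for (k in seq_len(dim(u)[3])) {
    n <- n + 1
    for (c in seq_len(dim(u)[4]))
      s <- s - v[i, j, k, c] * log(max(u[i, j, k, c], clamp))
  }
  s / n
}

# upsample-and-sum chain evaluated step by step with an explicit
# trilinear interpolation (half-voxel centre alignment) written in loops
oracle_trilinear <- function(x, out_dims) {
  dm <- dim(x)
  out <- array(NA_real_, c(out_dims, dm[4]))
  for (c in seq_len(dm[4])) for (i in seq_len(out_dims[1]))
    for (j in seq_len(out_dims[2])) for (k in seq_len(out_dims[3])) {
      src <- c((i - 0.5) * dm[1] / out_dims[1] - 0.5,
               (j - 0.5) * dm[2] / out_dims[2] - 0.5,
               (k - 0.5) * dm[3] / out_dims[3] - 0.5)
      src <- pmin(pmax(src, 0), dm[1:3] - 1)
      i0 <- pmin(floor(src), dm[1:3] - 2); i0 <- pmax(i0, 0)
      f <- src - i0
      acc <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
             (if (dz) f[3] else 1 - f[3])
        acc <- acc + w * x[min(i0[1] + dx + 1, dm[1]), min(i0[2] + dy + 1, dm[2]),
                           min(i0[3] + dz + 1, dm[3]), c]
      }
      out[i, j, k, c] <- acc
    }
  out
}

oracle_combine_dsv <- function(maps) {
  s <- maps[[1]]
  if (length(maps) > 1) for (m in maps[-1])
    s <- oracle_trilinear(s, dim(m)[1:3]) + m
  s
}

oracle_prd <- function(pred, truth, cl) {
  tp <- fp <- fn <- 0
  for (t in seq_along(pred)) {
    p <- pred[t] == cl; g <- truth[t] == cl
    if (p && g) tp <- tp + 1
    if (p && !g) fp <- fp + 1
    if (!p && g) fn <- fn + 1
  }
  c(precision = if (tp + fp > 0) tp / (tp + fp) * 100 else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) * 100 else 0,
    dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) * 100 else 100)
}

random_softmax <- function(dims) {
  u <- array(stats::rexp(prod(c(dims, 3))), c(dims, 3))
  s <- array(rep(apply(u, 1:3, sum), 3), dim(u))
  u / s
}

random_onehot <- function(dims) {
  lab <- array(sample(0:2, prod(dims), TRUE), dims)
  v <- array(0, c(dims, 3))
  for (c in 0:2) v[, , , c + 1][lab == c] <- 1
  v
}
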