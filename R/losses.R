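# Training objective: soft dice + cross-entropy on the softmax output.
#
# For one sample, per class c:  term_c = sum_i(u_ic v_ic) / (sum_i u_ic +
# sum_i v_ic + eps); the dice loss is -2/|C| * sum_c term_c, averaged over
# the batch; it lies in [-1, 0].  The cross-entropy is -sum_c v log(u),
# reduced to a mean over voxels by default so its magnitude does not grow
# with patch size (a plain sum is available via `reduction`).

as_prob_target <- function(u, v) {
  if (is.null(dim(u)) || is.null(dim(v)) || !all(dim(u) == dim(v)))
    stop("u and v must be arrays of identical shape")
  list(u = u, v = v, C = dim(u)[length(dim(u))])
}

#' Soft dice loss
#'
#' @param u softmax probabilities, array with classes on the last axis, or
#'   a list of such arrays (a batch; the loss is averaged over it).
#' @param v one-hot target of the same shape.
#' @param eps denominator guard for classes absent from both maps.
#' @param include_background include the background class in the average
#'   (default `TRUE`).
#' @return Scalar in `[-1, 0]`; `-1` for a perfect one-hot prediction.
#' @export
dice_loss <- function(u, v, eps = 1e-5, include_background = TRUE) {
  if (is.list(u)) return(mean(mapply(dice_loss, u, v,
                                     MoreArgs = list(eps = eps, include_background = include_background))))
  z <- as_prob_target(u, v)
  C <- z$C
  n <- length(u) / C
  um <- matrix(u, n, C); vm <- matrix(v, n, C)
  cls <- if (include_background) seq_len(C) else seq_len(C)[-1L]
  num <- colSums(um * vm)[cls]
  den <- (colSums(um) + colSums(vm))[cls] + eps
  -2 / length(cls) * sum(num / den)
}

#' Cross-entropy loss
#'
#' @inheritParams dice_loss
#' @param clamp lower bound applied to probabilities before the log.
#' @param reduction `"mean"` (per voxel, default) or `"sum"`.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(u, v, clamp = 1e-7, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (is.list(u)) return(mean(mapply(cross_entropy_loss, u, v,
                                     MoreArgs = list(clamp = clamp, reduction = reduction))))
  z <- as_prob_target(u, v)
  n <- length(u) / z$C
  s <- -sum(v * log(pmax(u, clamp)))
  if (reduction == "mean") s / n else s
}

#' Combined training loss
#'
#' The exact sum of the dice and cross-entropy components.
#'
#' @inheritParams dice_loss
#' @param ... passed to the component losses.
#' @return List with `total`, `dice` and `cross_entropy`.
#' @export
total_loss <- function(u, v, ...) {
  d <- dice_loss(u, v, ...)
  ce <- cross_entropy_loss(u, v)
  list(total = d + ce, dice = d, cross_entropy = ce)
}

# Loss and gradient with respect to the network logits for one sample.
# Backpropagates the combined objective through the softmax analytically
# (fused single pass in C++).
loss_and_grad <- function(logits, labels, num_classes, eps = 1e-5, clamp = 1e-7) {
  storage.mode(labels) <- "integer"
  cpp_loss_grad(logits, labels, num_classes, eps, clamp)
}
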