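# Deep supervision: secondary segmentation heads and the upsample-and-sum
# combination chain.

#' Secondary segmentation head
#'
#' A 1x1x1 convolution mapping decoder features at one resolution level to
#' `num_classes` score channels.
#'
#' @param features array `c(d1,d2,d3,F)` of decoder features.
#' @param w weight matrix `F x num_classes`.
#' @param b bias of length `num_classes`.
#' @return Score array `c(d1,d2,d3,num_classes)`.
#' @export
dsv_head <- function(features, w, b = numeric(ncol(w))) {
  dm <- dim(features)
  if (length(dm) != 4L) stop("features must be a 4-d array")
  if (dm[4] != nrow(w)) stop("feature channels do not match head weights")
  n <- prod(dm[1:3])
  out <- sweep(matrix(features, n, dm[4]) %*% w, 2L, b, "+")
  array(out, c(dm[1:3], ncol(w)))
}

#' Combine deep-supervision maps by upsample-and-sum
#'
#' Starting from the lowest-resolution map, each running sum is upsampled
#' (trilinearly) to the next map's grid and added to it, until the highest
#' resolution is reached.
#'
#' @param maps list of score arrays ordered coarsest to finest; each finer
#'   map's grid must equal the upsampling target of its predecessor.
#' @return Combined score array at the finest resolution.
#' @export
combine_dsv <- function(maps) {
  if (length(maps) == 0L) stop("need at least one map")
  s <- maps[[1L]]
  if (length(dim(s)) != 4L) stop("maps must be 4-d arrays")
  if (length(maps) > 1L) for (m in maps[-1L]) {
    dm <- dim(m)
    if (length(dm) != 4L || dm[4] != dim(s)[4])
      stop("maps must share the class-channel count")
    if (any(dm[1:3] < dim(s)[1:3]))
      stop("maps must be ordered coarsest to finest")
    s <- cpp_resize_fwd(s, as.integer(dm[1:3])) + m
  }
  s
}
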