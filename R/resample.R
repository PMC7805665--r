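# Grid resampling.
#
# The output grid for a spacing change has, per axis,
#   new_n = round(old_n * old_spacing / target_spacing)
# and output voxel centres map into the input grid with half-voxel centre
# alignment: src = (i + 0.5) * target/old - 0.5 (0-based, clamped).
# Images are interpolated with natural cubic (third-order) splines applied
# separably per axis; label masks use nearest-neighbour interpolation so the
# output value set is a subset of the input's.

resample_shape <- function(old_shape, old_spacing, target_spacing) {
  as.integer(round(old_shape * old_spacing / target_spacing))
}

axis_src_coords <- function(old_n, new_n, old_sp, new_sp) {
  src <- (seq_len(new_n) - 0.5) * (new_sp / old_sp) - 0.5
  pmin(pmax(src, 0), old_n - 1)
}

# new_n x old_n linear operator for natural-cubic-spline interpolation along
# one axis (cubic spline interpolation is linear in the data values)
spline_matrix <- function(old_n, new_n, old_sp, new_sp) {
  if (old_n == new_n && isTRUE(all.equal(old_sp, new_sp))) return(diag(old_n))
  src <- axis_src_coords(old_n, new_n, old_sp, new_sp)
  if (old_n == 1L) return(matrix(1, new_n, 1))
  S <- matrix(0, new_n, old_n)
  x <- seq_len(old_n) - 1
  for (j in seq_len(old_n)) {
    e <- numeric(old_n); e[j] <- 1
    S[, j] <- if (old_n < 4L) stats::approx(x, e, xout = src, rule = 2)$y
              else stats::spline(x, e, xout = src, method = "natural")$y
  }
  S
}

apply_axis_matrix <- function(arr, S, axis) {
  dm <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, dm[axis], prod(dm[-axis]))
  out <- S %*% m
  res <- array(out, c(nrow(S), dm[perm[2]], dm[perm[3]]))
  aperm(res, order(perm))
}

#' Resample a volume or label mask to a target spacing
#'
#' Images are interpolated with separable third-order (natural cubic)
#' splines; masks with nearest-neighbour interpolation, which guarantees the
#' output labels are a subset of the input label set.  The output shape per
#' axis is `round(shape * spacing / target_spacing)`.
#'
#' @param x a [ct_volume] or [ct_labelmask].
#' @param target_spacing numeric length-3, mm per axis, all > 0.
#' @param ... unused.
#' @return An object of the same class as `x` on the new grid.
#' @export
resample <- function(x, target_spacing, ...) UseMethod("resample")

check_target_spacing <- function(target_spacing) {
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target_spacing must be 3 positive finite values")
  as.numeric(target_spacing)
}

#' @rdname resample
#' @export
resample.ct_volume <- function(x, target_spacing, ...) {
  target_spacing <- check_target_spacing(target_spacing)
  old <- dim(x$data)
  new_shape <- resample_shape(old, x$spacing, target_spacing)
  arr <- x$data
  for (axis in 1:3) {
    if (new_shape[axis] == old[axis] && isTRUE(all.equal(x$spacing[axis], target_spacing[axis]))) next
    S <- spline_matrix(old[axis], new_shape[axis], x$spacing[axis], target_spacing[axis])
    arr <- apply_axis_matrix(arr, S, axis)
  }
  ct_volume(arr, spacing = target_spacing, affine = x$affine)
}

#' @rdname resample
#' @export
resample.ct_labelmask <- function(x, target_spacing, ...) {
  target_spacing <- check_target_spacing(target_spacing)
  old <- dim(x$labels)
  new_shape <- resample_shape(old, x$spacing, target_spacing)
  idx <- lapply(1:3, function(axis) {
    src <- axis_src_coords(old[axis], new_shape[axis], x$spacing[axis], target_spacing[axis])
    pmin(pmax(as.integer(round(src)) + 1L, 1L), old[axis])
  })
  arr <- x$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  ct_labelmask(arr, spacing = target_spacing, class_set = x$class_set, affine = x$affine)
}
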