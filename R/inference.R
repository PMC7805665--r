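# Patch-wise inference: half-overlap tiling, Gaussian importance
# weighting, mirror test-time augmentation, cross-resolution softmax
# ensembling, and export of attention/deep-supervision activation maps.

#' Gaussian patch importance weights
#'
#' Separable Gaussian centred on the patch with per-axis sigma equal to
#' one eighth of the patch size.  The maximum is exactly 1 at the patch
#' centre; values fall off toward the borders and are floored at `eps` so
#' voxels covered only by a patch border keep defined aggregates.
#'
#' @param patch_size integer length-3.
#' @param eps floor applied to the weights.
#' @return 3-d array of weights in `(0, 1]`.
#' @export
gaussian_weights <- function(patch_size, eps = 1e-6) {
  patch_size <- as.integer(patch_size)
  ax <- lapply(patch_size, function(n) {
    x <- seq_len(n) - 1
    ctr <- (n - 1) / 2
    sigma <- n / 8
    exp(-(x - ctr)^2 / (2 * sigma^2))
  })
  w <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  dim(w) <- patch_size
  w <- w / max(w)
  pmax(w, eps)
}

#' Tile corner positions for half-overlap sliding-window inference
#'
#' Strides by half the patch size per axis; the last tile is clamped to
#' the volume boundary so every voxel is covered by at least one tile.
#'
#' @param volume_shape integer length-3 (must be >= patch per axis).
#' @param patch_size integer length-3.
#' @return Integer matrix, one 1-based corner per row.
#' @export
tile_positions <- function(volume_shape, patch_size) {
  volume_shape <- as.integer(volume_shape); patch_size <- as.integer(patch_size)
  if (any(volume_shape < patch_size)) stop("volume smaller than patch; pad first")
  starts <- lapply(1:3, function(a) {
    stride <- max(patch_size[a] %/% 2L, 1L)
    last <- volume_shape[a] - patch_size[a] + 1L
    s <- seq.int(1L, last, by = stride)
    if (s[length(s)] != last) s <- c(s, last)
    s
  })
  as.matrix(expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

mirror_variants <- function() {
  v <- list(integer(0))
  for (axes in list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L)))
    v[[length(v) + 1L]] <- axes
  v
}

predict_patch <- function(network, patch, tta = TRUE) {
  variants <- if (tta) mirror_variants() else list(integer(0))
  acc <- NULL
  for (axes in variants) {
    p <- forward_pass(network, flip_axes(patch, axes), mode = "eval")
    p <- flip_axes(p, axes)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / length(variants)
}

#' Predict a whole volume by Gaussian-weighted patch stitching
#'
#' Tiles the (preprocessed) volume with half-overlapping patches, runs the
#' network on each tile — optionally averaging over all 8 mirror
#' reflections (test-time augmentation) — and aggregates the softmax maps
#' as `sum(w * p) / sum(w)` per voxel with the Gaussian importance
#' weights.  Volumes smaller than the patch are zero-padded symmetrically
#' and cropped after.
#'
#' @param network a trained `seg_network` (may be `NULL` when `patch_fun`
#'   is supplied).
#' @param volume a [ct_volume] already resampled/normalized to the plan.
#' @param plan a `seg_plan`.
#' @param tta average over all mirror reflections.
#' @param patch_fun optional `function(patch)` returning the per-patch
#'   class-probability array; replaces the network (useful for stubs and
#'   for validating the stitching arithmetic in isolation).
#' @return A `softmax_volume`: list with `probs` (4-d array, channels sum
#'   to 1 per voxel), `spacing`, `affine`.
#' @export
predict_volume <- function(network, volume, plan, tta = TRUE, patch_fun = NULL) {
  arr <- if (inherits(volume, "ct_volume")) volume$data else as.array(volume)
  spacing <- if (inherits(volume, "ct_volume")) volume$spacing else c(1, 1, 1)
  affine <- if (inherits(volume, "ct_volume")) volume$affine else NULL
  orig <- dim(arr)
  ps <- plan$patch_size
  padded <- pad_to_patch(arr, ps, 0)
  dm <- dim(padded$arr)
  C <- if (is.null(patch_fun)) network$spec$num_classes
       else dim(patch_fun(array(0, ps)))[4]
  w <- gaussian_weights(ps)
  num <- array(0, c(dm, C))
  den <- array(0, dm)
  tiles <- tile_positions(dm, ps)
  for (r in seq_len(nrow(tiles))) {
    corner <- tiles[r, ]
    ix <- corner[1] + seq_len(ps[1]) - 1L
    iy <- corner[2] + seq_len(ps[2]) - 1L
    iz <- corner[3] + seq_len(ps[3]) - 1L
    tilearr <- padded$arr[ix, iy, iz, drop = FALSE]
    probs <- if (is.null(patch_fun)) predict_patch(network, tilearr, tta = tta)
             else patch_fun(tilearr)
    num[ix, iy, iz, ] <- num[ix, iy, iz, , drop = FALSE] + probs * array(as.vector(w), dim(probs))
    den[ix, iy, iz] <- den[ix, iy, iz] + w
  }
  probs <- num / array(as.vector(den), dim(num))
  lo <- padded$lo
  probs <- probs[lo[1] + seq_len(orig[1]), lo[2] + seq_len(orig[2]),
                 lo[3] + seq_len(orig[3]), , drop = FALSE]
  structure(list(probs = probs, spacing = spacing, affine = affine),
            class = "softmax_volume")
}

#' Voxel-wise argmax of a softmax volume
#'
#' Ties break deterministically toward the lowest class index.
#'
#' @param sv a `softmax_volume`.
#' @return A [ct_labelmask].
#' @export
predict_labels <- function(sv) {
  dm <- dim(sv$probs)
  m <- matrix(sv$probs, prod(dm[1:3]), dm[4])
  lab <- max.col(m, ties.method = "first") - 1L
  ct_labelmask(array(lab, dm[1:3]), spacing = sv$spacing,
               class_set = 0:(dm[4] - 1L), affine = sv$affine)
}

#' Ensemble full- and low-resolution predictions
#'
#' The low-resolution softmax maps are resampled trilinearly onto the
#' full-resolution grid, averaged (unweighted) with the full-resolution
#' maps, and only then converted to a label map by voxel-wise argmax.
#'
#' @param full_res `softmax_volume` on the target grid.
#' @param low_res `softmax_volume` on a coarser grid of the same patient.
#' @return A [ct_labelmask] on the full-resolution grid.
#' @export
assemble_predictions <- function(full_res, low_res) {
  tgt <- dim(full_res$probs)
  lr <- cpp_resize_fwd(low_res$probs, as.integer(tgt[1:3]))
  if (!all(dim(lr) == tgt)) stop("geometry mismatch after resampling")
  # renormalize the interpolated map before averaging two simplex fields
  n <- prod(tgt[1:3])
  lm <- matrix(lr, n, tgt[4])
  lm <- lm / rowSums(lm)
  avg <- (matrix(full_res$probs, n, tgt[4]) + lm) / 2
  sv <- structure(list(probs = array(avg, tgt), spacing = full_res$spacing,
                       affine = full_res$affine), class = "softmax_volume")
  predict_labels(sv)
}

#' Export attention and deep-supervision activation maps
#'
#' Runs tiled eval-mode forward passes and stitches, per attention gate,
#' the coefficient map (upsampled to patch resolution), and per
#' deep-supervision level the softmax of its secondary segmentation map.
#' Maps are written as NIfTI files into `out_dir`.
#'
#' @param network a trained `seg_network`.
#' @param volume preprocessed [ct_volume].
#' @param plan a `seg_plan`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the exported arrays (also on disk).
#' @export
export_activation_maps <- function(network, volume, plan, out_dir) {
  spec <- network$spec
  if (spec$ag_levels == 0L && spec$dsv_levels == 0L) {
    warning("network has neither attention gates nor deep supervision; nothing to export")
    return(invisible(list()))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arr <- if (inherits(volume, "ct_volume")) volume$data else as.array(volume)
  spacing <- if (inherits(volume, "ct_volume")) volume$spacing else c(1, 1, 1)
  orig <- dim(arr)
  ps <- plan$patch_size
  padded <- pad_to_patch(arr, ps, 0)
  dm <- dim(padded$arr)
  w <- gaussian_weights(ps)
  C <- spec$num_classes
  maps <- list()
  den <- array(0, dm)
  add_map <- function(maps, key, tile_val, ix, iy, iz, channels) {
    if (is.null(maps[[key]])) maps[[key]] <- array(0, c(dm, channels))
    maps[[key]][ix, iy, iz, ] <- maps[[key]][ix, iy, iz, , drop = FALSE] +
      tile_val * array(as.vector(w), dim(tile_val))
    maps
  }
  tiles <- tile_positions(dm, ps)
  for (r in seq_len(nrow(tiles))) {
    corner <- tiles[r, ]
    ix <- corner[1] + seq_len(ps[1]) - 1L
    iy <- corner[2] + seq_len(ps[2]) - 1L
    iz <- corner[3] + seq_len(ps[3]) - 1L
    g <- net_graph(network, padded$arr[ix, iy, iz, drop = FALSE], train = FALSE)
    for (nm in names(g$alpha_ids)) {
      a <- ag_value(g$tape, g$alpha_ids[[nm]])
      a <- cpp_resize_fwd(a, as.integer(ps))
      maps <- add_map(maps, paste0("attention_", nm), a, ix, iy, iz, 1L)
    }
    if (spec$dsv_levels > 0L) for (l in seq_len(spec$dsv_levels)) {
      h <- ag_value(g$tape, g$head_ids[[l]])
      h <- softmax_channels(h)
      h <- cpp_resize_fwd(h, as.integer(ps))
      maps <- add_map(maps, sprintf("dsv_level%d", l - 1L), h, ix, iy, iz, C)
    }
    den[ix, iy, iz] <- den[ix, iy, iz] + w
  }
  lo <- padded$lo
  out <- list()
  for (key in names(maps)) {
    m <- maps[[key]] / array(as.vector(den), dim(maps[[key]]))
    m <- m[lo[1] + seq_len(orig[1]), lo[2] + seq_len(orig[2]),
           lo[3] + seq_len(orig[3]), , drop = FALSE]
    out[[key]] <- m
    nch <- dim(m)[4]
    for (ch in seq_len(nch)) {
      suffix <- if (nch > 1L) sprintf("_class%d", ch - 1L) else ""
      write_nifti(array(m[, , , ch], orig),
                  file.path(out_dir, paste0(key, suffix, ".nii.gz")),
                  spacing = spacing)
    }
  }
  invisible(out)
}
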