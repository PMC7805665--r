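# Patch sampling for training.  Patches are cut on the fly; a batch-level
# guarantee forces at least one patch per batch to contain foreground,
# which stabilizes training under the heavy class imbalance of organ/tumor
# CT (background dominates, tumors are rare).

case_arrays <- function(case) {
  img <- if (inherits(case$image, "ct_volume")) case$image$data else as.array(case$image)
  lab <- if (inherits(case$mask, "ct_labelmask")) case$mask$labels else as.array(case$mask)
  if (!all(dim(img) == dim(lab))) stop("case image/mask shape mismatch")
  list(img = img, lab = lab)
}

pad_to_patch <- function(arr, patch_size, fill) {
  dm <- dim(arr)
  pad <- pmax(patch_size - dm, 0L)
  if (all(pad == 0L)) return(list(arr = arr, lo = c(0L, 0L, 0L)))
  lo <- pad %/% 2L
  out <- array(fill, pmax(dm, patch_size))
  out[lo[1] + seq_len(dm[1]), lo[2] + seq_len(dm[2]), lo[3] + seq_len(dm[3])] <- arr
  list(arr = out, lo = lo)
}

#' Sample one training patch
#'
#' Cuts an image/label patch of the requested size.  Without the foreground
#' constraint the patch corner is uniform over valid positions; with it,
#' the patch is centred on a uniformly chosen foreground voxel (clipped to
#' the volume bounds).  Volumes smaller than the patch are zero-padded
#' symmetrically first (zero is the background label; images are assumed
#' normalized, where zero is the foreground mean).
#'
#' Uses the current RNG stream; wrap in a seeded context for
#' reproducibility.
#'
#' @param case list with `image` ([ct_volume] or array, normalized) and
#'   `mask` ([ct_labelmask] or integer array).
#' @param patch_size integer length-3.
#' @param force_foreground centre the patch on a foreground voxel.
#' @return List with `image`, `labels` (arrays of dim `patch_size`),
#'   `case_id`, and `corner` (1-based corner in the padded grid).
#' @export
sample_patch <- function(case, patch_size, force_foreground = FALSE) {
  patch_size <- as.integer(patch_size)
  ca <- case_arrays(case)
  pi <- pad_to_patch(ca$img, patch_size, 0)
  pl <- pad_to_patch(ca$lab, patch_size, 0L)
  dm <- dim(pi$arr)
  hi <- dm - patch_size + 1L
  if (force_foreground) {
    fg <- which(pl$arr > 0L)
    if (length(fg) == 0L) {
      warning("case has no foreground voxels; sampling a random patch instead")
      force_foreground <- FALSE
    } else {
      v <- fg[sample.int(length(fg), 1L)] - 1L
      ctr <- c(v %% dm[1], (v %/% dm[1]) %% dm[2], v %/% (dm[1] * dm[2])) + 1L
      corner <- pmin(pmax(ctr - patch_size %/% 2L, 1L), hi)
    }
  }
  if (!force_foreground)
    corner <- vapply(hi, function(h) sample.int(h, 1L), integer(1))
  ix <- corner[1] + seq_len(patch_size[1]) - 1L
  iy <- corner[2] + seq_len(patch_size[2]) - 1L
  iz <- corner[3] + seq_len(patch_size[3]) - 1L
  list(image = pi$arr[ix, iy, iz, drop = FALSE],
       labels = pl$arr[ix, iy, iz, drop = FALSE],
       case_id = case$id, corner = corner)
}

#' Sample a training batch with a foreground guarantee
#'
#' Draws `batch_size` patches from randomly chosen cases; one randomly
#' designated patch is forced to contain foreground (so every batch has at
#' least one non-background voxel, unless the whole dataset is background,
#' which degrades to a warning).
#'
#' @param cases list of cases (see [sample_patch()]).
#' @param batch_size number of patches (>= 1).
#' @param patch_size integer length-3.
#' @return List of patch pairs.
#' @export
sample_batch <- function(cases, batch_size, patch_size) {
  if (length(cases) == 0L) stop("empty case list")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  forced <- sample.int(batch_size, 1L)
  lapply(seq_len(batch_size), function(b) {
    case <- cases[[sample.int(length(cases), 1L)]]
    sample_patch(case, patch_size, force_foreground = b == forced)
  })
}
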