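#' Compute a dataset intensity/geometry fingerprint
#'
#' The fingerprint parameterizes preprocessing: the per-axis median voxel
#' spacing over cases, the median shape after resampling to that spacing,
#' and the pooled statistics of the intensities lying inside the
#' segmentation masks (any non-zero label): the 0.5th and 99.5th
#' percentiles used for clipping, and the mean and standard deviation used
#' for z-score normalization.
#'
#' Percentiles use linear interpolation between order statistics; the
#' standard deviation is the population form (divisor `n`), matching the
#' pooled-voxel reading of the statistics.
#'
#' @param cases list of cases, each a list with elements `image`
#'   (a [ct_volume]) and `mask` (a [ct_labelmask]).
#' @return An object of class `dataset_fingerprint` with fields
#'   `median_spacing`, `median_shape`, `fg_p005`, `fg_p995`, `fg_mean`,
#'   `fg_std`, `n_cases`.
#' @export
compute_fingerprint <- function(cases) {
  if (length(cases) < 1L) stop("need at least one case")
  spac <- t(vapply(cases, function(cs) cs$image$spacing, numeric(3)))
  median_spacing <- apply(spac, 2L, stats::median)
  shapes <- t(vapply(cases, function(cs)
    as.numeric(resample_shape(dim(cs$image$data), cs$image$spacing, median_spacing)),
    numeric(3)))
  median_shape <- apply(shapes, 2L, stats::median)
  fg <- unlist(lapply(cases, function(cs) {
    if (is.null(cs$mask)) stop("every case needs a mask to fingerprint foreground intensities")
    if (!all(dim(cs$mask$labels) == dim(cs$image$data)))
      stop("image/mask shape mismatch in case")
    cs$image$data[cs$mask$labels > 0L]
  }), use.names = FALSE)
  if (length(fg) == 0L) stop("dataset has no foreground voxels")
  q <- stats::quantile(fg, c(0.005, 0.995), names = FALSE, type = 7)
  m <- mean(fg)
  s <- sqrt(mean((fg - m)^2))
  structure(list(median_spacing = median_spacing, median_shape = median_shape,
                 fg_p005 = q[1], fg_p995 = q[2], fg_mean = m, fg_std = s,
                 n_cases = length(cases)),
            class = "dataset_fingerprint")
}

#' @export
print.dataset_fingerprint <- function(x, ...) {
  cat("<dataset_fingerprint> ", x$n_cases, " case(s)\n",
      "  median spacing: ", paste(signif(x$median_spacing, 4), collapse = " x "), " mm\n",
      "  median shape:   ", paste(round(x$median_shape), collapse = " x "), " voxels\n",
      sprintf("  foreground: p0.5 %.3f, p99.5 %.3f, mean %.3f, sd %.3f\n",
              x$fg_p005, x$fg_p995, x$fg_mean, x$fg_std), sep = "")
  invisible(x)
}

#' Clip and z-score normalize a volume using a dataset fingerprint
#'
#' Intensities are clipped to the foreground 0.5/99.5 percentiles and then
#' z-scored with the foreground mean and standard deviation:
#' `(clip(x, p005, p995) - mean) / sd`.
#'
#' @param vol a [ct_volume].
#' @param fingerprint a `dataset_fingerprint`.
#' @return The normalized [ct_volume].
#' @export
normalize_volume <- function(vol, fingerprint) {
  if (!inherits(fingerprint, "dataset_fingerprint")) stop("need a dataset_fingerprint")
  if (fingerprint$fg_std <= 0) stop("degenerate dataset: foreground standard deviation is zero")
  d <- pmin(pmax(vol$data, fingerprint$fg_p005), fingerprint$fg_p995)
  d <- (d - fingerprint$fg_mean) / fingerprint$fg_std
  dim(d) <- dim(vol$data)
  ct_volume(d, spacing = vol$spacing, affine = vol$affine)
}

#' Target spacing for the low-resolution variant
#'
#' The dataset spacing is doubled (isotropically) until the median shape of
#' the resampled data holds fewer than four times the voxels of one input
#' patch: the smallest `k >= 0` with
#' `prod(median_shape / 2^k) < 4 * prod(patch_size)` gives
#' `median_spacing * 2^k`.
#'
#' @param fingerprint a `dataset_fingerprint`.
#' @param patch_size integer length-3 patch shape in voxels.
#' @return List with `target_spacing`, `k` (number of halvings) and the
#'   projected `median_shape` at that spacing.
#' @export
lowres_spacing <- function(fingerprint, patch_size) {
  patch_size <- as.numeric(patch_size)
  if (length(patch_size) != 3L || any(patch_size <= 0)) stop("patch_size must be 3 positive values")
  budget <- 4 * prod(patch_size)
  k <- 0L
  while (prod(fingerprint$median_shape / 2^k) >= budget) k <- k + 1L
  list(target_spacing = fingerprint$median_spacing * 2^k, k = k,
       median_shape = fingerprint$median_shape / 2^k)
}
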