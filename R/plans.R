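# Training plans: resolution variant, target spacing, patch size, per-axis
# downsampling counts, batch size.  Shipped presets reproduce the published
# per-task configurations for the kidney (KiTS19), liver (MDC Task03) and
# pancreas (MDC Task07) tumor-segmentation tasks.

.plan_presets <- list(
  kidney = list(
    full = list(median_shape = c(511, 511, 136), patch_size = c(160, 160, 48),
                levels_per_axis = c(5, 5, 3), batch_size = 2),
    low  = list(median_shape = c(247, 247, 127), patch_size = c(128, 128, 80),
                levels_per_axis = c(5, 5, 4), batch_size = 2)),
  liver = list(
    full = list(median_shape = c(482, 512, 512), patch_size = c(96, 128, 128),
                levels_per_axis = c(5, 5, 5), batch_size = 2),
    low  = list(median_shape = c(189, 201, 201), patch_size = c(96, 128, 128),
                levels_per_axis = c(5, 5, 5), batch_size = 2)),
  pancreas = list(
    full = list(median_shape = c(96, 512, 512), patch_size = c(40, 192, 160),
                levels_per_axis = c(3, 5, 5), batch_size = 2),
    low  = list(median_shape = c(88, 299, 299), patch_size = c(64, 128, 128),
                levels_per_axis = c(3, 5, 5), batch_size = 2))
)

#' Construct and validate a training plan
#'
#' @param task_name label for the task.
#' @param resolution `"full"` or `"low"`.
#' @param patch_size integer length-3; each axis must be divisible by
#'   `2^levels` for its level count.
#' @param levels_per_axis integer length-3 downsampling counts (0..5).
#' @param batch_size patches per optimization step (>= 1).
#' @param target_spacing mm per axis, or `NA` when the spacing is to be
#'   derived from a dataset fingerprint at preprocessing time.
#' @param median_shape reference median dataset shape (informational).
#' @return An object of class `seg_plan`.
#' @export
make_plan <- function(task_name, resolution = c("full", "low"),
                      patch_size, levels_per_axis, batch_size = 2,
                      target_spacing = NA_real_, median_shape = NULL) {
  resolution <- match.arg(resolution)
  patch_size <- as.integer(patch_size)
  levels_per_axis <- as.integer(levels_per_axis)
  if (length(patch_size) != 3L || any(patch_size < 1L)) stop("patch_size must be 3 positive integers")
  if (length(levels_per_axis) != 3L || any(levels_per_axis < 0L) || any(levels_per_axis > 5L))
    stop("levels_per_axis must be 3 integers in 0..5")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  bad <- patch_size %% 2L^levels_per_axis != 0L
  if (any(bad))
    stop("patch size not divisible by 2^levels on axis ", paste(which(bad), collapse = ", "))
  # deepest feature-map extent below 8 is tolerated but flagged (the level
  # counts are authoritative; the size-8 guideline is only advisory)
  deepest <- patch_size / 2L^levels_per_axis
  if (any(deepest < 8))
    message("note: deepest feature maps have extent ",
            paste(deepest, collapse = "x"), " (< 8 on some axis)")
  structure(list(task_name = task_name, resolution = resolution,
                 target_spacing = as.numeric(target_spacing),
                 patch_size = patch_size, levels_per_axis = levels_per_axis,
                 batch_size = as.integer(batch_size),
                 median_shape = median_shape),
            class = "seg_plan")
}

#' Shipped per-task plan presets
#'
#' Returns the published configuration (input patch size, per-axis
#' downsampling counts, batch size, reference median shape) for the three
#' CT tumor-segmentation tasks, in full- or low-resolution variants.  The
#' target spacing of a preset is dataset-derived (median spacing for the
#' full-resolution variant, [lowres_spacing()] for the low-resolution one),
#' so it is `NA` until a fingerprint is available.
#'
#' @param task `"kidney"`, `"liver"` or `"pancreas"`.
#' @param resolution `"full"` or `"low"`.
#' @return A `seg_plan`.
#' @export
plan_for_task <- function(task, resolution = c("full", "low")) {
  resolution <- match.arg(resolution)
  if (!task %in% names(.plan_presets))
    stop("unknown task preset '", task, "'; available: ",
         paste(names(.plan_presets), collapse = ", "))
  p <- .plan_presets[[task]][[resolution]]
  suppressMessages(make_plan(task, resolution, p$patch_size, p$levels_per_axis,
                             p$batch_size, median_shape = p$median_shape))
}

#' Scaled-down plan for the synthetic phantom study
#'
#' A small configuration (32^3 patches, three resolution levels, batch 2)
#' sized so that training and inference run in minutes on one CPU.
#'
#' @return A `seg_plan`.
#' @export
tiny_plan <- function() {
  make_plan("phantom", "full", patch_size = c(32, 32, 32),
            levels_per_axis = c(3, 3, 3), batch_size = 2,
            target_spacing = c(1, 1, 1))
}

#' @export
print.seg_plan <- function(x, ...) {
  cat("<seg_plan> ", x$task_name, " (", x$resolution, " resolution)\n",
      "  patch size:  ", paste(x$patch_size, collapse = " x "), "\n",
      "  levels/axis: ", paste(x$levels_per_axis, collapse = ", "), "\n",
      "  batch size:  ", x$batch_size, "\n", sep = "")
  if (!all(is.na(x$target_spacing)))
    cat("  target spacing: ", paste(signif(x$target_spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Serialize a plan or fingerprint to JSON
#' @param x a `seg_plan` or `dataset_fingerprint`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_obj <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
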