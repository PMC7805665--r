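#' Construct a CT volume
#'
#' A `ct_volume` bundles a 3-d intensity grid with its per-axis voxel
#' spacing (mm) and the NIfTI affine carried through unchanged.  Intensities
#' are Hounsfield-like before normalization and unitless afterwards.
#'
#' @param data 3-d numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   affine built from `spacing`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must have exactly 3 axes")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "ct_volume")
}

#' Construct a label mask
#'
#' Integer voxel-wise labels over an ordered class set with 0 = background.
#' A mask shares the geometry (shape and spacing) of its paired volume.
#'
#' @param labels 3-d integer array.
#' @param spacing voxel size in mm per axis.
#' @param class_set ordered label values, first entry 0.
#' @param affine optional 4x4 affine.
#' @return An object of class `ct_labelmask`.
#' @export
ct_labelmask <- function(labels, spacing = c(1, 1, 1), class_set = 0:2, affine = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("mask labels must have exactly 3 axes")
  storage.mode(labels) <- "integer"
  if (class_set[1] != 0L) stop("class_set must start with 0 (background)")
  bad <- setdiff(unique(as.vector(labels)), as.integer(class_set))
  if (length(bad)) stop("mask contains labels outside class_set: ", paste(bad, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(labels = labels, spacing = spacing,
                 class_set = as.integer(class_set), affine = affine),
            class = "ct_labelmask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.ct_labelmask <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = max(x$class_set) + 1L)
  cat("<ct_labelmask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, counts: ", paste(sprintf("%d=%d", x$class_set, tab[x$class_set + 1L]),
                                 collapse = ", "), "\n", sep = "")
  invisible(x)
}

nifti_spacing <- function(img) {
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  as.numeric(pd[1:3])
}

#' Read a CT case from NIfTI files
#'
#' Reads an image volume and (optionally) its paired segmentation mask,
#' validating that both share a grid shape.  Geometry (spacing, affine) is
#' taken from the NIfTI headers.
#'
#' @param image_path path to the image `.nii`/`.nii.gz`.
#' @param mask_path optional path to the label mask.
#' @param class_set label values allowed in the mask.
#' @return A list with elements `image` (a [ct_volume]) and `mask`
#'   (a [ct_labelmask] or `NULL`).
#' @export
read_case <- function(image_path, mask_path = NULL, class_set = 0:2) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  img <- RNifti::readNifti(image_path)
  vol <- ct_volume(array(as.numeric(img), dim(img)[1:3]),
                   spacing = nifti_spacing(img),
                   affine = unclass(RNifti::xform(img)))
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
    m <- RNifti::readNifti(mask_path)
    if (!all(dim(m)[1:3] == dim(vol$data)))
      stop("mask shape (", paste(dim(m)[1:3], collapse = "x"),
           ") does not match image shape (", paste(dim(vol$data), collapse = "x"), ")")
    mask <- ct_labelmask(array(as.integer(round(m)), dim(m)[1:3]),
                         spacing = nifti_spacing(m), class_set = class_set,
                         affine = unclass(RNifti::xform(m)))
  }
  list(image = vol, mask = mask)
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [ct_volume], [ct_labelmask], or plain 3-d array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing spacing to record when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = NULL) {
  if (inherits(x, "ct_volume")) {
    arr <- x$data; spacing <- x$spacing
  } else if (inherits(x, "ct_labelmask")) {
    arr <- x$labels; spacing <- x$spacing
    storage.mode(arr) <- "double"
  } else {
    arr <- as.array(x)
    if (is.null(spacing)) spacing <- c(1, 1, 1)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a JSON list of cases, each with `id`, `image` and
#' optionally `mask` paths (relative paths resolved against the manifest's
#' directory).
#'
#' @param path manifest JSON path.
#' @return A list of case descriptors.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path)
  base <- dirname(normalizePath(path))
  lapply(man$cases, function(cs) {
    for (f in c("image", "mask")) {
      if (!is.null(cs[[f]]) && !grepl("^/", cs[[f]]))
        cs[[f]] <- file.path(base, cs[[f]])
    }
    cs
  })
}

load_cases <- function(manifest, with_masks = TRUE) {
  lapply(manifest, function(cs) {
    case <- read_case(cs$image, if (with_masks) cs$mask else NULL)
    case$id <- cs$id
    case
  })
}
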