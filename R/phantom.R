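# Synthetic phantoms: a smooth ellipsoidal "organ" (label 1) at a random
# pose containing a small spherical "tumor" (label 2), over a background
# whose intensity distribution overlaps the organ's — the class structure
# and imbalance of abdominal organ/tumor CT (background dominates, the
# organ is next, the tumor is rare).  Every stage of the pipeline is
# exercisable on phantoms without external data.

#' Phantom generator configuration
#'
#' Defaults emulate soft-tissue CT contrast: adjacent class means are
#' separated by about one noise standard deviation, making the task
#' learnable from spatial context but not voxel-wise trivial; the organ
#' occupies well under 10% of the volume.
#'
#' @param grid_size voxels per axis.
#' @param spacing mm per axis (may be anisotropic).
#' @param organ_axes range (min, max) of the organ ellipsoid semi-axes, mm.
#' @param tumor_radius range of the tumor sphere radius, mm; the maximum
#'   must fit inside the smallest organ semi-axis.
#' @param mu_bg,mu_organ,mu_tumor class mean intensities (HU-like).
#' @param sd_tissue within-class texture standard deviations
#'   (background, organ, tumor).
#' @param sd_noise global additive noise standard deviation.
#' @param edge_sigma smoothing (mm) of the class-mean image before noise,
#'   imitating partial-volume blur at boundaries.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid_size = c(48, 48, 48), spacing = c(1, 1, 1),
                           organ_axes = c(8, 13), tumor_radius = c(3, 5),
                           mu_bg = 40, mu_organ = 65, mu_tumor = 90,
                           sd_tissue = c(5, 5, 5), sd_noise = 25,
                           edge_sigma = 0.8) {
  grid_size <- as.integer(grid_size); spacing <- as.numeric(spacing)
  if (any(grid_size < 8L)) stop("grid too small")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (max(tumor_radius) >= min(organ_axes))
    stop("infeasible geometry: tumor radius ", max(tumor_radius),
         " cannot fit inside an organ with smallest semi-axis ", min(organ_axes))
  if (min(grid_size * spacing) < 2 * max(organ_axes) + 4)
    stop("infeasible geometry: organ does not fit in the grid")
  structure(list(grid_size = grid_size, spacing = spacing,
                 organ_axes = as.numeric(organ_axes),
                 tumor_radius = as.numeric(tumor_radius),
                 mu = c(bg = mu_bg, organ = mu_organ, tumor = mu_tumor),
                 sd_tissue = as.numeric(sd_tissue), sd_noise = sd_noise,
                 edge_sigma = edge_sigma),
            class = "phantom_config")
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate one phantom case
#'
#' Samples an ellipsoid pose and a tumor centre (inside the eroded organ),
#' labels the grid, and draws intensities from the per-class Gaussian
#' model with partial-volume smoothing and additive noise.  Fully
#' deterministic given the seed.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return List with `image` ([ct_volume]), `mask` ([ct_labelmask]) and
#'   `id`.
#' @export
generate_phantom <- function(config, seed = 1L) {
  with_seed(seed, {
    gs <- config$grid_size; sp <- config$spacing
    axes <- sort(stats::runif(3, config$organ_axes[1], config$organ_axes[2]))
    R <- random_rotation()
    amax <- max(axes)
    ext <- gs * sp
    ctr <- stats::runif(3, amax + 1, ext - amax - 1)
    # world (mm) coordinates of voxel centres
    pos <- list(( seq_len(gs[1]) - 0.5) * sp[1],
                ( seq_len(gs[2]) - 0.5) * sp[2],
                ( seq_len(gs[3]) - 0.5) * sp[3])
    grid <- cbind(rep.int(pos[[1]], gs[2] * gs[3]),
                  rep.int(rep(pos[[2]], each = gs[1]), gs[3]),
                  rep(pos[[3]], each = gs[1] * gs[2]))
    rel <- sweep(grid, 2L, ctr) %*% R
    q <- (rel[, 1] / axes[1])^2 + (rel[, 2] / axes[2])^2 + (rel[, 3] / axes[3])^2
    lab <- as.integer(q <= 1)
    r_t <- stats::runif(1, config$tumor_radius[1], config$tumor_radius[2])
    # tumor centre: inside the organ, eroded so the sphere (dilated by one
    # voxel as safety margin) fits entirely; verified voxel-wise
    margin <- max(sp)
    shrink <- 1 - (r_t + margin) / axes
    if (any(shrink <= 0)) stop("infeasible geometry: tumor cannot fit in organ")
    placed <- FALSE
    for (try in 1:100) {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      tctr <- ctr + as.vector((u * shrink * axes) %*% t(R))
      d2 <- (grid[, 1] - tctr[1])^2 + (grid[, 2] - tctr[2])^2 + (grid[, 3] - tctr[3])^2
      if (all(q[d2 <= (r_t + margin)^2] <= 1)) { placed <- TRUE; break }
    }
    if (!placed) stop("infeasible geometry: tumor placement failed")
    lab[d2 <= r_t^2] <- 2L
    lab <- array(lab, gs)
    counts <- tabulate(lab + 1L, 3L)
    if (!(counts[1] > counts[2] && counts[2] > counts[3]))
      stop("degenerate phantom: class counts not background > organ > tumor")
    base <- array(config$mu[lab + 1L], gs)
    if (config$edge_sigma > 0)
      base <- cpp_gauss_smooth(base, config$edge_sigma / sp)
    img <- base +
      array(stats::rnorm(prod(gs), 0, config$sd_tissue[lab + 1L]), gs) +
      array(stats::rnorm(prod(gs), 0, config$sd_noise), gs)
    list(image = ct_volume(img, spacing = sp),
         mask = ct_labelmask(lab, spacing = sp),
         id = sprintf("phantom_%04d", seed))
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` NIfTI case pairs plus a JSON manifest compatible with
#' [read_manifest()]/[load_cases()].
#'
#' @param n number of cases.
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; case `i` uses a derived child seed.
#' @return The manifest path, invisibly; the manifest lists case ids and
#'   relative file paths.
#' @export
generate_dataset <- function(n, config = phantom_config(), out_dir, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  cases <- lapply(seq_len(n), function(i) {
    cs <- generate_phantom(config, seed = derive_seed(seed, i))
    id <- sprintf("case_%03d", i)
    write_nifti(cs$image, file.path(out_dir, paste0(id, "_image.nii.gz")))
    write_nifti(cs$mask, file.path(out_dir, paste0(id, "_mask.nii.gz")))
    list(id = id, image = paste0(id, "_image.nii.gz"),
         mask = paste0(id, "_mask.nii.gz"))
  })
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(cases = cases), manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' Generate phantom cases in memory
#'
#' Convenience wrapper producing `n` ready-to-use cases without touching
#' disk (used by the scaled-down training studies and tests).
#'
#' @inheritParams generate_dataset
#' @return List of cases (each with `image`, `mask`, `id`).
#' @export
generate_cases <- function(n, config = phantom_config(), seed = 1L) {
  lapply(seq_len(n), function(i) generate_phantom(config, seed = derive_seed(seed, i)))
}
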