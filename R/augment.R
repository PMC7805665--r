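# On-the-fly augmentation of training patches: random rotations, random
# scaling, random elastic deformations, gamma correction, and mirroring.
# Spatial transforms are applied identically to the image (trilinear
# interpolation) and the labels (nearest neighbour, so the label set is
# preserved); gamma acts on the image only.

#' Augmentation configuration
#'
#' Defaults follow the conventions of on-the-fly 3D medical-image
#' augmentation pipelines: each transform fires independently with its own
#' probability.
#'
#' @param rotation_deg maximal rotation per axis, degrees.
#' @param rotation_p probability of applying a rotation.
#' @param scale_range uniform range for the isotropic scale factor.
#' @param scale_p probability of scaling.
#' @param elastic_alpha range for the deformation magnitude (voxels of
#'   displacement before smoothing scales it down).
#' @param elastic_sigma range for the Gaussian smoothing sigma (voxels).
#' @param elastic_p probability of elastic deformation.
#' @param gamma_range uniform range for the gamma exponent.
#' @param gamma_p probability of gamma correction.
#' @param mirror_p per-axis probability of mirroring.
#' @param mirror_axes axes eligible for mirroring.
#' @return An `augment_config` object.
#' @export
augment_config <- function(rotation_deg = 30, rotation_p = 0.2,
                           scale_range = c(0.85, 1.25), scale_p = 0.2,
                           elastic_alpha = c(0, 200), elastic_sigma = c(9, 13),
                           elastic_p = 0.2,
                           gamma_range = c(0.7, 1.5), gamma_p = 0.3,
                           mirror_p = 0.5, mirror_axes = 1:3) {
  stopifnot(rotation_deg >= 0, diff(scale_range) >= 0, diff(gamma_range) >= 0,
            all(c(rotation_p, scale_p, elastic_p, gamma_p, mirror_p) >= 0),
            all(c(rotation_p, scale_p, elastic_p, gamma_p, mirror_p) <= 1))
  structure(list(rotation_deg = rotation_deg, rotation_p = rotation_p,
                 scale_range = scale_range, scale_p = scale_p,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 elastic_p = elastic_p, gamma_range = gamma_range,
                 gamma_p = gamma_p, mirror_p = mirror_p,
                 mirror_axes = as.integer(mirror_axes)),
            class = "augment_config")
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

base_grid <- function(dm) {
  cbind(rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
        rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[3]),
        rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]))
}

#' Augment a patch pair
#'
#' Applies the configured random transforms using the current RNG stream.
#' Output shapes equal input shapes; out-of-bounds image regions are filled
#' with the patch minimum, labels with background.
#'
#' @param pair list with `image` and `labels` arrays (from [sample_patch()]).
#' @param config an [augment_config()].
#' @return The augmented pair (other fields carried through).
#' @export
augment_patch <- function(pair, config = augment_config()) {
  img <- pair$image; lab <- pair$labels
  dm <- dim(img)
  do_rot <- stats::runif(1) < config$rotation_p
  do_scale <- stats::runif(1) < config$scale_p
  do_elastic <- stats::runif(1) < config$elastic_p
  if (do_rot || do_scale || do_elastic) {
    ctr <- (dm - 1) / 2
    A <- diag(3)
    if (do_rot)
      A <- rotation_matrix(stats::runif(3, -1, 1) * config$rotation_deg * pi / 180)
    if (do_scale)
      A <- A / stats::runif(1, config$scale_range[1], config$scale_range[2])
    g <- base_grid(dm)
    coords <- sweep(g, 2L, ctr) %*% t(A)
    coords <- sweep(coords, 2L, ctr, "+")
    if (do_elastic) {
      alpha <- stats::runif(1, config$elastic_alpha[1], config$elastic_alpha[2])
      sigma <- stats::runif(1, config$elastic_sigma[1], config$elastic_sigma[2])
      for (ax in 1:3) {
        noise <- array(stats::runif(prod(dm), -1, 1), dm)
        disp <- cpp_gauss_smooth(noise, rep(sigma, 3)) * alpha
        coords[, ax] <- coords[, ax] + as.vector(disp)
      }
    }
    img <- cpp_warp(img, coords, as.integer(dm), 1L, min(img))
    lab <- cpp_warp(array(as.double(lab), dm), coords, as.integer(dm), 0L, 0)
    lab <- array(as.integer(round(lab)), dm)
    img <- array(img, dm)
  }
  if (stats::runif(1) < config$gamma_p) {
    gamma <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
    rng <- range(img)
    if (diff(rng) > 0)
      img <- ((img - rng[1]) / diff(rng))^gamma * diff(rng) + rng[1]
  }
  for (ax in config$mirror_axes) {
    if (stats::runif(1) < config$mirror_p) {
      img <- flip_axes(img, ax)
      lab <- flip_axes(lab, ax)
    }
  }
  pair$image <- img
  pair$labels <- lab
  pair
}
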