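# Additive attention gates.
#
# A gate compares skip-connection features x^l (fine grid, F_l channels)
# with a gating signal g from the next-coarser decoder level (F_g
# channels).  On the coarse grid it computes
#   q   = psi' relu(Wx' x_down + Wg' g + b_g) + b_psi
#   alpha = sigmoid(q)
# where the linear maps are 1x1x1 convolutions and x_down is x^l brought to
# g's grid by a strided 1x1x1 convolution folded into Wx.  The coefficient
# map is upsampled trilinearly to x^l's grid and multiplies every channel.

#' Attention-gate parameters
#'
#' @param F_l channels of the gated skip features.
#' @param F_g channels of the gating signal.
#' @param F_int intermediate channels (default `F_l %/% 2`, at least 1).
#' @param stride per-axis factor between the fine and the coarse grid.
#' @param seed seed for the He-normal initialization of `W_x`/`W_g`.
#' @return An object of class `ag_params` with fields `wx` (`F_l x F_int`),
#'   `wg` (`F_g x F_int`), `bg`, `psi` (`F_int x 1`), `bpsi`.
#' @export
ag_params <- function(F_l, F_g, F_int = max(F_l %/% 2L, 1L),
                      stride = c(2, 2, 2), seed = 1L) {
  if (F_int < 1L) stop("F_int must be >= 1")
  p <- with_seed(seed, list(
    wx = matrix(stats::rnorm(F_l * F_int, 0, sqrt(2 / F_l)), F_l, F_int),
    wg = matrix(stats::rnorm(F_g * F_int, 0, sqrt(2 / F_g)), F_g, F_int),
    bg = numeric(F_int),
    psi = matrix(stats::rnorm(F_int, 0, sqrt(2 / F_int)), F_int, 1),
    bpsi = 0))
  p$F_l <- as.integer(F_l); p$F_g <- as.integer(F_g); p$F_int <- as.integer(F_int)
  p$stride <- as.integer(stride)
  class(p) <- "ag_params"
  p
}

#' Pass-through initialization of attention gates
#'
#' Re-initializes gate parameters so that a freshly built network lets all
#' feature vectors pass at all spatial locations: the `psi` weights are set
#' to zero and its bias to 10, giving `alpha = sigmoid(10) ~ 0.99995`
#' everywhere while keeping the gate fully trainable; `W_x`/`W_g` are
#' He-normal and `b_g` zero.
#'
#' @param x an `ag_params` object or a `seg_network` (all its gates are
#'   re-initialized in place and the network returned).
#' @param seed seed for the He-normal draws.
#' @return The re-initialized object.
#' @export
init_pass_through <- function(x, seed = 1L) UseMethod("init_pass_through")

#' @export
init_pass_through.ag_params <- function(x, seed = 1L) {
  p <- with_seed(seed, {
    x$wx[] <- stats::rnorm(length(x$wx), 0, sqrt(2 / x$F_l))
    x$wg[] <- stats::rnorm(length(x$wg), 0, sqrt(2 / x$F_g))
    x
  })
  p$bg[] <- 0
  p$psi[] <- 0
  p$bpsi <- 10
  p
}

#' @export
init_pass_through.seg_network <- function(x, seed = 1L) {
  spec <- x$spec
  if (spec$ag_levels == 0L) return(x)
  with_seed(seed, {
    for (l in 0:(spec$ag_levels - 1L)) {
      for (nm in c("wx", "wg")) {
        key <- sprintf("ag%d.%s", l, nm)
        pi <- x$param_info[[key]]
        x$params[[key]][] <- stats::rnorm(prod(pi$dim), 0, sqrt(2 / pi$fan_in))
      }
      x$params[[sprintf("ag%d.bg", l)]][] <- 0
      x$params[[sprintf("ag%d.psi", l)]][] <- 0
      x$params[[sprintf("ag%d.bpsi", l)]][] <- 10
    }
    x
  })
}

#' Compute attention coefficients
#'
#' Evaluates the additive attention gate for given skip features and gating
#' signal and returns the coefficient map on the fine grid.
#'
#' @param x_l array `c(d1,d2,d3,F_l)`, skip features at the fine grid.
#' @param g array `c(d1,d2,d3)/stride x F_g`, gating signal at the coarse grid.
#' @param params an [ag_params()] object.
#' @return An object of class `attention_map`: list with `alpha` (3-d array
#'   on the fine grid, values in `[0,1]`) and `alpha_coarse`.
#' @export
attention_coefficients <- function(x_l, g, params) {
  if (!inherits(params, "ag_params")) stop("params must be ag_params")
  dx <- dim(x_l); dg <- dim(g)
  if (length(dx) != 4L || length(dg) != 4L) stop("x_l and g must be 4-d arrays")
  if (dx[4] != params$F_l) stop("x_l has ", dx[4], " channels, params expect ", params$F_l)
  if (dg[4] != params$F_g) stop("g has ", dg[4], " channels, params expect ", params$F_g)
  if (!all(dx[1:3] %/% params$stride == dg[1:3]))
    stop("g grid must be the x_l grid reduced by the gate stride")
  ix <- seq.int(1L, dx[1], by = params$stride[1])
  iy <- seq.int(1L, dx[2], by = params$stride[2])
  iz <- seq.int(1L, dx[3], by = params$stride[3])
  xs <- x_l[ix, iy, iz, , drop = FALSE]
  n <- prod(dg[1:3])
  xd <- matrix(xs, n, params$F_l) %*% params$wx
  gq <- sweep(matrix(g, n, params$F_g) %*% params$wg, 2L, params$bg, "+")
  q <- pmax(xd + gq, 0) %*% params$psi + params$bpsi
  alpha_coarse <- array(1 / (1 + exp(-q)), c(dg[1:3], 1L))
  alpha <- cpp_resize_fwd(alpha_coarse, as.integer(dx[1:3]))
  structure(list(alpha = array(alpha, dx[1:3]),
                 alpha_coarse = array(alpha_coarse, dg[1:3])),
            class = "attention_map")
}

#' Apply an attention map to feature maps
#'
#' Element-wise multiplication: every channel of `x_l` is scaled by the
#' same per-voxel coefficient.
#'
#' @param x_l array `c(d1,d2,d3,F_l)`.
#' @param alpha an `attention_map` or a 3-d array matching `x_l`'s grid.
#' @return The gated features, same shape as `x_l`.
#' @export
apply_gate <- function(x_l, alpha) {
  if (inherits(alpha, "attention_map")) alpha <- alpha$alpha
  dx <- dim(x_l)
  if (length(dx) == 3L) dim(x_l) <- dx <- c(dx, 1L)
  if (!all(dim(alpha) == dx[1:3]))
    stop("attention map shape does not match the feature grid")
  x_l * array(as.vector(alpha), dx)
}
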