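#' Specify a segmentation network
#'
#' Describes a 3D encoder-decoder topology: the U-Net variant downsamples
#' with max-pooling and upsamples with trilinear interpolation; the V-Net
#' variant is fully convolutional (non-overlapping strided and transposed
#' convolutions, kernel = stride = 2 on active axes).  Feature counts start
#' at `base_features` and double at each level up to `feature_cap`.  Each
#' context/localization module is two blocks of
#' convolution (3x3x3) -> dropout -> instance norm -> leaky ReLU.
#' Additive attention gates act on the skip connections of the topmost
#' `ag_levels` decoder levels; deep-supervision heads sit on the topmost
#' `dsv_levels` decoder levels.
#'
#' An axis whose level budget in `levels_per_axis` is exhausted is no
#' longer downsampled at deeper levels (pool/stride factor 1 on that axis).
#'
#' @param variant `"vnet"` or `"unet"`.
#' @param base_features feature maps at the highest resolution (default 30).
#' @param levels_per_axis integer length-3, downsampling count per axis (<= 5).
#' @param num_classes segmentation classes including background.
#' @param dropout_p dropout probability inside modules.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param feature_cap maximum channel count.
#' @param ag_levels number of topmost decoder levels with attention gates.
#' @param dsv_levels number of topmost decoder levels with supervision heads
#'   (0 disables deep supervision; then a single 1x1x1 output head is used).
#' @param in_channels input image channels.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(variant = c("vnet", "unet"), base_features = 30,
                         levels_per_axis = c(5, 5, 5), num_classes = 3,
                         dropout_p = 0.1, leaky_slope = 0.01,
                         feature_cap = 320, ag_levels = 2, dsv_levels = 3,
                         in_channels = 1) {
  variant <- match.arg(variant)
  levels_per_axis <- as.integer(levels_per_axis)
  if (length(levels_per_axis) != 3L || any(levels_per_axis < 0L) || any(levels_per_axis > 5L))
    stop("levels_per_axis must be 3 integers in 0..5")
  L <- max(levels_per_axis)
  if (L < 1L) stop("need at least one downsampling level")
  if (base_features < 1) stop("base_features must be >= 1")
  ag_levels <- as.integer(ag_levels); dsv_levels <- as.integer(dsv_levels)
  if (dsv_levels > L) stop("dsv_levels cannot exceed the number of levels (", L, ")")
  if (ag_levels > dsv_levels && dsv_levels > 0L)
    stop("ag_levels must not exceed dsv_levels")
  if (dsv_levels == 0L && ag_levels > 0L)
    stop("attention gates require dsv_levels >= ag_levels (set dsv_levels or disable gates)")
  if (ag_levels > L) stop("ag_levels cannot exceed the number of levels")
  structure(list(variant = variant, base_features = as.integer(base_features),
                 levels_per_axis = levels_per_axis, num_classes = as.integer(num_classes),
                 dropout_p = dropout_p, leaky_slope = leaky_slope,
                 feature_cap = as.integer(feature_cap),
                 ag_levels = ag_levels, dsv_levels = dsv_levels,
                 in_channels = as.integer(in_channels)),
            class = "network_spec")
}

spec_levels <- function(spec) max(spec$levels_per_axis)

spec_features <- function(spec, l) as.integer(min(spec$base_features * 2^l, spec$feature_cap))

# per-axis pool/stride factor for the transition into level l (1-based l)
spec_stride <- function(spec, l) ifelse(l <= spec$levels_per_axis, 2L, 1L)

ag_fint <- function(F_l) max(F_l %/% 2L, 1L)

# --- parameter inventory ----------------------------------------------------

conv_block_info <- function(prefix, cin, cout) {
  setNames(list(
    list(kind = "conv_w", dim = c(3, 3, 3, cin, cout), fan_in = 27 * cin),
    list(kind = "bias", dim = cout),
    list(kind = "gamma", dim = cout),
    list(kind = "beta", dim = cout)),
    paste0(prefix, c(".w", ".b", ".gamma", ".beta")))
}

network_param_info <- function(spec) {
  L <- spec_levels(spec)
  info <- list()
  for (l in 0:L) {
    fl <- spec_features(spec, l)
    cin1 <- if (l == 0L) spec$in_channels
            else if (spec$variant == "vnet") fl
            else spec_features(spec, l - 1L)
    info <- c(info, conv_block_info(sprintf("enc%d.b1", l), cin1, fl),
                    conv_block_info(sprintf("enc%d.b2", l), fl, fl))
    if (l > 0L && spec$variant == "vnet") {
      f <- spec_stride(spec, l)
      info[[sprintf("down%d.w", l)]] <-
        list(kind = "conv_w", dim = c(f, spec_features(spec, l - 1L), fl),
             fan_in = prod(f) * spec_features(spec, l - 1L))
      info[[sprintf("down%d.b", l)]] <- list(kind = "bias", dim = fl)
    }
  }
  for (l in (L - 1L):0) {
    fl <- spec_features(spec, l); fup <- spec_features(spec, l + 1L)
    if (spec$variant == "vnet") {
      f <- spec_stride(spec, l + 1L)
      info[[sprintf("up%d.w", l)]] <-
        list(kind = "conv_w", dim = c(f, fl, fup), fan_in = fup)
      info[[sprintf("up%d.b", l)]] <- list(kind = "bias", dim = fl)
      cat_in <- fl + fl
    } else {
      cat_in <- fup + fl
    }
    info <- c(info, conv_block_info(sprintf("dec%d.b1", l), cat_in, fl),
                    conv_block_info(sprintf("dec%d.b2", l), fl, fl))
  }
  if (spec$ag_levels > 0L) for (l in 0:(spec$ag_levels - 1L)) {
    fl <- spec_features(spec, l); fg <- spec_features(spec, l + 1L)
    fi <- ag_fint(fl)
    info[[sprintf("ag%d.wx", l)]]   <- list(kind = "ag_w", dim = c(fl, fi), fan_in = fl)
    info[[sprintf("ag%d.wg", l)]]   <- list(kind = "ag_w", dim = c(fg, fi), fan_in = fg)
    info[[sprintf("ag%d.bg", l)]]   <- list(kind = "bias", dim = fi)
    info[[sprintf("ag%d.psi", l)]]  <- list(kind = "ag_psi_w", dim = c(fi, 1))
    info[[sprintf("ag%d.bpsi", l)]] <- list(kind = "ag_bpsi", dim = 1)
  }
  if (spec$dsv_levels > 0L) {
    for (l in 0:(spec$dsv_levels - 1L)) {
      fl <- spec_features(spec, l)
      info[[sprintf("dsv%d.w", l)]] <- list(kind = "head_w", dim = c(fl, spec$num_classes), fan_in = fl)
      info[[sprintf("dsv%d.b", l)]] <- list(kind = "bias", dim = spec$num_classes)
    }
  } else {
    f0 <- spec_features(spec, 0L)
    info[["out.w"]] <- list(kind = "head_w", dim = c(f0, spec$num_classes), fan_in = f0)
    info[["out.b"]] <- list(kind = "bias", dim = spec$num_classes)
  }
  info
}

init_param <- function(pi) {
  n <- prod(pi$dim)
  v <- switch(pi$kind,
    conv_w  = ,
    ag_w    = ,
    head_w  = stats::rnorm(n, 0, sqrt(2 / pi$fan_in)),
    gamma   = rep(1, n),
    ag_bpsi = 10,
    ag_psi_w = rep(0, n),
    rep(0, n))
  if (length(pi$dim) > 1L) dim(v) <- pi$dim
  v
}

#' Build a segmentation network
#'
#' Allocates and initializes all trainable parameters for a
#' [network_spec()]: convolution weights from the He normal distribution
#' (sd `sqrt(2/fan_in)`), biases zero, instance-norm affine at identity,
#' and attention gates in the pass-through regime (see
#' [init_pass_through()]).
#'
#' @param spec a `network_spec`.
#' @param patch_size optional length-3 patch shape; validated against the
#'   per-axis level counts (each axis divisible by `2^levels`).
#' @param seed integer seed controlling the random initialization.
#' @return An object of class `seg_network`.
#' @export
build_network <- function(spec, patch_size = NULL, seed = 1L) {
  if (!inherits(spec, "network_spec")) stop("spec must be a network_spec")
  if (!is.null(patch_size)) {
    bad <- as.integer(patch_size) %% 2L^spec$levels_per_axis != 0L
    if (any(bad))
      stop("patch axis ", paste(which(bad), collapse = ", "),
           " not divisible by 2^levels")
  }
  info <- network_param_info(spec)
  net <- structure(list(spec = spec, param_info = info,
                        params = vector("list", length(info))),
                   class = "seg_network")
  names(net$params) <- names(info)
  he_init(net, seed = seed)
}

#' Count trainable parameters
#'
#' @param network a `seg_network`.
#' @return Total number of scalar trainable parameters.
#' @export
count_parameters <- function(network) {
  sum(vapply(network$params, length, integer(1)))
}

#' @export
print.seg_network <- function(x, ...) {
  sp <- x$spec
  cat("<seg_network> ", toupper(sp$variant),
      if (sp$ag_levels > 0) "-AG", if (sp$dsv_levels > 0) "-DSV",
      ": base ", sp$base_features, ", levels (",
      paste(sp$levels_per_axis, collapse = ","), "), ",
      format(count_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# --- forward pass -----------------------------------------------------------

softmax_channels <- function(logits) {
  dm <- dim(logits)
  n <- prod(dm[1:3])
  C <- dm[4]
  m <- matrix(logits, n, C)
  mx <- m[, 1L]
  for (c in seq_len(C)[-1L]) mx <- pmax(mx, m[, c])
  m <- exp(m - mx)
  p <- m / rowSums(m)
  dim(p) <- dm
  p
}

# Build the full computation graph for one input patch on a fresh tape.
# Returns ids for the logits, per-gate attention maps (coarse-grid sigmoid
# output already upsampled to the skip grid) and per-level DSV head maps.
net_graph <- function(net, patch, train = FALSE) {
  spec <- net$spec
  L <- spec_levels(spec)
  if (length(dim(patch)) == 3L) dim(patch) <- c(dim(patch), 1L)
  if (dim(patch)[4] != spec$in_channels) stop("input channel mismatch")
  bad <- dim(patch)[1:3] %% 2L^spec$levels_per_axis != 0L
  if (any(bad)) stop("input axis ", paste(which(bad), collapse = ", "),
                     " not divisible by 2^levels")
  tape <- ag_tape()
  pids <- new.env(parent = emptyenv())
  P <- function(name) {
    id <- pids[[name]]
    if (is.null(id)) {
      if (is.null(net$params[[name]])) stop("unknown parameter ", name)
      id <- ag_push(tape, net$params[[name]])
      pids[[name]] <- id
    }
    id
  }
  blk <- function(xid, prefix, need_gx = TRUE) {
    force(need_gx)
    cid <- op_conv3(tape, xid, P(paste0(prefix, ".w")), P(paste0(prefix, ".b")),
                    need_gx = need_gx)
    did <- op_dropout(tape, cid, spec$dropout_p, train)
    op_in_lrelu(tape, did, P(paste0(prefix, ".gamma")), P(paste0(prefix, ".beta")),
                spec$leaky_slope)
  }
  xid <- op_input(tape, patch)
  skips <- vector("list", L + 1L)
  cur <- xid
  for (l in 0:L) {
    if (l > 0L) {
      f <- spec_stride(spec, l)
      cur <- if (spec$variant == "vnet")
        op_blockdown(tape, cur, P(sprintf("down%d.w", l)), P(sprintf("down%d.b", l)), f)
      else op_maxpool(tape, cur, f)
    }
    cur <- blk(cur, sprintf("enc%d.b1", l), need_gx = l > 0L)
    cur <- blk(cur, sprintf("enc%d.b2", l))
    skips[[l + 1L]] <- cur
  }
  dec <- skips[[L + 1L]]
  alpha_ids <- list()
  head_ids <- vector("list", max(spec$dsv_levels, 0L))
  for (l in (L - 1L):0) {
    skip <- skips[[l + 1L]]
    gated <- skip
    if (l < spec$ag_levels) {
      f <- spec_stride(spec, l + 1L)
      xd <- op_strided1(tape, skip, P(sprintf("ag%d.wx", l)), f)
      gq <- op_conv1(tape, dec, P(sprintf("ag%d.wg", l)), P(sprintf("ag%d.bg", l)))
      qs <- op_relu(tape, op_add(tape, xd, gq))
      qa <- op_conv1(tape, qs, P(sprintf("ag%d.psi", l)), P(sprintf("ag%d.bpsi", l)))
      ac <- op_sigmoid(tape, qa)
      al <- op_resize(tape, ac, dim(ag_value(tape, skip))[1:3])
      alpha_ids[[sprintf("ag%d", l)]] <- al
      gated <- op_mul_alpha(tape, skip, al)
    }
    f <- spec_stride(spec, l + 1L)
    up <- if (spec$variant == "vnet")
      op_blockup(tape, dec, P(sprintf("up%d.w", l)), P(sprintf("up%d.b", l)), f)
    else op_resize(tape, dec, dim(ag_value(tape, skip))[1:3])
    cat_id <- op_concat(tape, up, gated)
    dec <- blk(cat_id, sprintf("dec%d.b1", l))
    dec <- blk(dec, sprintf("dec%d.b2", l))
    if (l < spec$dsv_levels)
      head_ids[[l + 1L]] <- op_conv1(tape, dec, P(sprintf("dsv%d.w", l)), P(sprintf("dsv%d.b", l)))
  }
  logits <- if (spec$dsv_levels > 0L) {
    # upsample-and-sum chain, coarsest head first
    s <- head_ids[[spec$dsv_levels]]
    if (spec$dsv_levels > 1L) for (l in (spec$dsv_levels - 1L):1) {
      tgt <- dim(ag_value(tape, head_ids[[l]]))[1:3]
      s <- op_add(tape, op_resize(tape, s, tgt), head_ids[[l]])
    }
    s
  } else {
    op_conv1(tape, dec, P("out.w"), P("out.b"))
  }
  list(tape = tape, logits = logits, alpha_ids = alpha_ids,
       head_ids = head_ids, pids = pids)
}

#' Run a forward pass
#'
#' @param network a `seg_network`.
#' @param patch 3-d array (or 4-d with a channel axis) matching the plan's
#'   patch size; each axis must be divisible by `2^levels`.
#' @param mode `"eval"` (deterministic; dropout off) or `"train"`.
#' @return Softmax class probabilities, array of dim `c(patch, num_classes)`.
#' @export
forward_pass <- function(network, patch, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  g <- net_graph(network, patch, train = mode == "train")
  softmax_channels(ag_value(g$tape, g$logits))
}
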