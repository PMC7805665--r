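# Small shared helpers.

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

# Derive a well-separated 31-bit child seed from (seed, index).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587 + 1)
}

#' Decimal half-up rounding
#'
#' Rounds half away from zero at a fixed number of decimals, with a small
#' guard against binary floating-point representation error, so that
#' averages of values printed to that precision round the way decimal
#' arithmetic would (e.g. `mean(c(81.22, 52.99))` reports 67.11).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

onehot_labels <- function(labels, num_classes) {
  dm <- dim(labels)
  v <- matrix(0, prod(dm), num_classes)
  v[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  array(v, c(dm, num_classes))
}

flip_axes <- function(a, axes) {
  if (length(axes) == 0L) return(a)
  dm <- dim(a)
  idx <- lapply(seq_along(dm), function(ax)
    if (ax %in% axes) rev(seq_len(dm[ax])) else seq_len(dm[ax]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}
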