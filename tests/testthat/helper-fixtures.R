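# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, create) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- create()
  .fixtures[[name]]
}

# a small network spec that keeps unit tests fast (8^3-compatible)
small_spec <- function(variant = "vnet", ag = TRUE, dropout_p = 0) {
  network_spec(variant = variant, base_features = 4, levels_per_axis = c(2, 2, 1),
               num_classes = 3, dropout_p = dropout_p,
               ag_levels = if (ag) 2 else 0, dsv_levels = if (ag) 2 else 0)
}

small_net <- function(variant = "vnet", ag = TRUE, seed = 7) {
  fx(paste0("net_", variant, "_", ag, "_", seed),
     function() build_network(small_spec(variant, ag), seed = seed))
}

# phantoms shared across files (default config: 48^3, <10% foreground)
shared_phantoms <- function(n = 6) {
  stopifnot(n <= 6)
  fx("phantoms6", function() generate_cases(6, phantom_config(), seed = 1234))[seq_len(n)]
}

rand_array <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

# a plain V-Net whose output is a fixed softmax constant everywhere:
# all weights zero, output bias = logits of the target probabilities
constant_network <- function(probs, levels = c(1, 1, 1), base = 2) {
  spec <- network_spec(variant = "vnet", base_features = base,
                       levels_per_axis = levels, num_classes = length(probs),
                       dropout_p = 0, ag_levels = 0, dsv_levels = 0)
  net <- build_network(spec, seed = 1)
  net$params <- lapply(net$params, function(p) p * 0)
  for (nm in names(net$params))
    if (grepl("\\.gamma$", nm)) net$params[[nm]][] <- 1
  net$params[["out.b"]] <- log(probs)
  net
}
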