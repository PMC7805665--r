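# High-level pipeline helpers tying preprocessing, training and evaluation
# together, plus the scaled-down phantom study used to validate the whole
# method end-to-end on one CPU.

#' Preprocess one case for a plan
#'
#' Resamples image (cubic spline) and mask (nearest neighbour) to the
#' target spacing and applies clip + z-score normalization from the
#' dataset fingerprint.
#'
#' @param case list with `image` and optional `mask`.
#' @param fingerprint a `dataset_fingerprint`.
#' @param target_spacing defaults to the fingerprint's median spacing.
#' @return The preprocessed case.
#' @export
preprocess_case <- function(case, fingerprint,
                            target_spacing = fingerprint$median_spacing) {
  img <- case$image
  if (!all(abs(img$spacing - target_spacing) < 1e-9))
    img <- resample(img, target_spacing)
  case$image <- normalize_volume(img, fingerprint)
  if (!is.null(case$mask) && !all(abs(case$mask$spacing - target_spacing) < 1e-9))
    case$mask <- resample(case$mask, target_spacing)
  case
}

#' Scaled-down network configuration for phantom studies
#'
#' A V-Net sized for 32^3 patches: 8 base features, three levels per axis;
#' with (`ag = TRUE`) or without attention gates and deep supervision.
#'
#' @param ag attach attention gates (2 levels) and deep supervision
#'   (3 levels).
#' @return A [network_spec()].
#' @export
tiny_spec <- function(ag = TRUE) {
  network_spec(variant = "vnet", base_features = 8, levels_per_axis = c(3, 3, 3),
               num_classes = 3, ag_levels = if (ag) 2L else 0L,
               dsv_levels = if (ag) 3L else 0L)
}

mean_composite <- function(network, cases, plan, tta = FALSE) {
  vals <- vapply(cases, function(cs) {
    sv <- predict_volume(network, cs$image, plan, tta = tta)
    evaluate_case(predict_labels(sv), cs$mask)$composite_dice
  }, numeric(1))
  mean(vals)
}

#' End-to-end phantom study
#'
#' Generates a phantom dataset, preprocesses it, trains a scaled-down
#' attention-gated deeply-supervised V-Net (and optionally an identically
#' budgeted plain V-Net), and evaluates composite dice on the training
#' cases and on held-out phantoms.  The default budget (12 training cases,
#' batch 2, 50 epochs = 300 gradient steps) runs in minutes on one CPU.
#'
#' @param seed master seed for data, initialization and sampling.
#' @param n_train,n_test training and held-out case counts.
#' @param epochs training epochs (6 iterations each at the defaults).
#' @param lr Adam learning rate for this short schedule.
#' @param with_plain also train the plain V-Net baseline.
#' @param config phantom generator configuration.
#' @param verbose print training progress.
#' @return List with `train_composite`, `heldout_composite` (AG+DSV
#'   model), optionally `heldout_composite_plain`, and the fitted
#'   `network`.
#' @export
phantom_study <- function(seed = 1L, n_train = 12L, n_test = 6L, epochs = 50L,
                          lr = 1e-3, with_plain = TRUE,
                          config = phantom_config(), verbose = FALSE) {
  plan <- tiny_plan()
  train_raw <- generate_cases(n_train, config, seed = derive_seed(seed, 100L))
  test_raw <- generate_cases(n_test, config, seed = derive_seed(seed, 200L))
  fp <- compute_fingerprint(train_raw)
  train_cs <- lapply(train_raw, preprocess_case, fingerprint = fp)
  test_cs <- lapply(test_raw, preprocess_case, fingerprint = fp)
  net <- build_network(tiny_spec(ag = TRUE), plan$patch_size,
                       seed = derive_seed(seed, 300L))
  fit <- train_model(net, train_cs, plan, epochs = epochs, lr = lr,
                     seed = derive_seed(seed, 400L), verbose = verbose)
  out <- list(
    train_composite = mean_composite(fit$network, train_cs, plan),
    heldout_composite = mean_composite(fit$network, test_cs, plan),
    network = fit$network, log = fit$log, fingerprint = fp)
  if (with_plain) {
    plain <- build_network(tiny_spec(ag = FALSE), plan$patch_size,
                           seed = derive_seed(seed, 300L))
    pfit <- train_model(plain, train_cs, plan, epochs = epochs, lr = lr,
                        seed = derive_seed(seed, 400L), verbose = verbose)
    out$heldout_composite_plain <- mean_composite(pfit$network, test_cs, plan)
  }
  out
}
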