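test_that("He initialization has the predicted spread and zero biases", {
  spec <- network_spec(variant = "unet", base_features = 30,
                       levels_per_axis = c(2, 2, 2), ag_levels = 0, dsv_levels = 0)
  net <- build_network(spec, seed = 42)
  w <- net$params[["enc1.b1.w"]]   # 3x3x3 conv with 30 input channels
  expect_identical(dim(w), c(3L, 3L, 3L, 30L, 60L))
  expect_equal(sd(w), sqrt(2 / (27 * 30)), tolerance = 0.05 * sqrt(2 / (27 * 30)))
  expect_lt(abs(mean(w)), 3 * sqrt(2 / (27 * 30)) / sqrt(length(w)) * 5)
  for (nm in grep("\\.b$", names(net$params), value = TRUE))
    expect_true(all(net$params[[nm]] == 0), info = nm)
  # determinism
  net2 <- build_network(spec, seed = 42)
  expect_identical(net$params, net2$params)
  net3 <- build_network(spec, seed = 43)
  expect_false(identical(net$params, net3$params))
})

test_that("plateau schedule reduces the rate per the 30-epoch/0.2 rule", {
  # strictly improving losses: no reduction over 100 epochs
  st <- train_state(initial_lr = 3e-5)
  for (e in 1:100) st <- schedule_step(st, 1 - e * 0.01)
  expect_equal(st$lr, 3e-5)
  # constant loss from epoch 1: first reduction completes at epoch 31
  st <- train_state(initial_lr = 3e-5)
  lrs <- numeric(0)
  for (e in 1:31) { st <- schedule_step(st, 0.5); lrs <- c(lrs, st$lr) }
  expect_equal(lrs[30], 3e-5)
  expect_equal(lrs[31], 6e-6)
  # three reductions: 3e-5 -> 6e-6 -> 1.2e-6 -> 2.4e-7 < 1e-6 -> stop
  for (e in 32:91) st <- schedule_step(st, 0.5)
  expect_equal(st$lr, 3e-5 * 0.2^3, tolerance = 1e-12)
  expect_true(should_stop(st))
})

test_that("schedule state machine matches an independent simulation", {
  set.seed(71)
  for (rep in 1:5) {
    losses <- cumsum(rnorm(200, 0, 0.3)) + rnorm(200, 0, 0.05)
    st <- train_state(initial_lr = 3e-5)
    # independent step-by-step simulation of the written rule
    ema <- NA; best <- Inf; since <- 0; lr <- 3e-5
    for (l in losses) {
      st <- schedule_step(st, l)
      ema <- if (is.na(ema)) l else 0.9 * ema + 0.1 * l
      if (ema < best - 1e-5) { best <- ema; since <- 0 } else since <- since + 1
      if (since >= 30) { lr <- lr * 0.2; since <- 0 }
      expect_equal(st$lr, lr, tolerance = 1e-15)
      expect_equal(st$loss_ema, ema, tolerance = 1e-12)
    }
  }
})

test_that("stopping rule: learning-rate floor and epoch cap", {
  st <- train_state(initial_lr = 3e-5)
  st$lr <- 2.4e-7; st$epoch <- 200L
  expect_true(should_stop(st))
  st$lr <- 3e-5; st$epoch <- 1000L
  expect_true(should_stop(st))
  st$epoch <- 10L
  expect_false(should_stop(st))
})

test_that("five-fold splits partition 210 cases into 42/168", {
  ids <- sprintf("case_%03d", 1:210)
  folds <- make_folds(ids, k = 5, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$val_ids, 42)
    expect_length(f$train_ids, 168)
    expect_length(intersect(f$val_ids, f$train_ids), 0)
  }
  allval <- unlist(lapply(folds, `[[`, "val_ids"))
  expect_setequal(allval, ids)
  expect_identical(length(allval), 210L)
  expect_identical(make_folds(ids, 5, seed = 3), folds)
  expect_error(make_folds(ids[1:3], 5), "fewer cases")
})

test_that("learning rate is non-increasing with exact 0.2 steps", {
  set.seed(72)
  st <- train_state(initial_lr = 1e-3)
  lrs <- numeric(0)
  for (l in rnorm(150, 0, 0.01)) { st <- schedule_step(st, l); lrs <- c(lrs, st$lr) }
  expect_true(all(diff(lrs) <= 0))
  distinct <- unique(lrs)
  if (length(distinct) > 1)
    expect_equal(distinct[-1] / distinct[-length(distinct)],
                 rep(0.2, length(distinct) - 1), tolerance = 1e-12)
})

test_that("weight decay changes the learned parameters", {
  cs <- shared_phantoms(1)[[1]]
  fp <- compute_fingerprint(list(cs))
  cs <- preprocess_case(cs, fp)
  plan <- make_plan("t", "full", c(16, 16, 16), c(2, 2, 1), 2)
  spec <- network_spec(variant = "vnet", base_features = 2, levels_per_axis = c(2, 2, 1),
                       dropout_p = 0, ag_levels = 0, dsv_levels = 0)
  net <- build_network(spec, plan$patch_size, seed = 4)
  f0 <- train_model(net, list(cs), plan, epochs = 5, lr = 1e-3, weight_decay = 0, seed = 5)
  f1 <- train_model(net, list(cs), plan, epochs = 5, lr = 1e-3, weight_decay = 1e-2, seed = 5)
  n0 <- sqrt(sum(unlist(f0$final_network$params)^2))
  n1 <- sqrt(sum(unlist(f1$final_network$params)^2))
  expect_false(isTRUE(all.equal(n0, n1)))
  expect_lt(n1, n0)  # decay shrinks the parameter norm
})

test_that("an epoch iterates ceiling(cases / batch) batches and logs them", {
  cases <- lapply(shared_phantoms(3), function(cs) {
    fp <- compute_fingerprint(shared_phantoms(3))
    preprocess_case(cs, fp)
  })
  plan <- make_plan("t", "full", c(16, 16, 16), c(2, 2, 1), 2)
  spec <- network_spec(variant = "vnet", base_features = 2, levels_per_axis = c(2, 2, 1),
                       dropout_p = 0, ag_levels = 0, dsv_levels = 0)
  net <- build_network(spec, plan$patch_size, seed = 6)
  fit <- train_model(net, cases, plan, epochs = 2, lr = 1e-3, seed = 7)
  expect_identical(nrow(fit$log), 2L)
  expect_named(fit$log, c("epoch", "loss", "dice_loss", "ce_loss", "ema", "lr"))
  expect_true(all(is.finite(fit$log$loss)))
})
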