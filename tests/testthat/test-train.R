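test_that("early stopping halts after exactly `patience` bad epochs", {
  # validation loss worsens from the start: best epoch 1, stop at 1+patience
  tr <- early_stop_trace(seq(1, 3, length.out = 40), patience = 10)
  expect_equal(tr$best_epoch, 1)
  expect_equal(tr$stop_epoch, 11)
  expect_true(tr$stopped_early)

  # improvement resets the counter
  tr2 <- early_stop_trace(c(5, 4, 4.5, 4.6, 3, rep(3.5, 10)), patience = 10)
  expect_equal(tr2$best_epoch, 5)
  expect_equal(tr2$stop_epoch, 15)
  expect_true(tr2$stopped_early)

  # monotone improvement never stops early
  tr3 <- early_stop_trace(seq(5, 1, length.out = 20), patience = 10)
  expect_equal(tr3$best_epoch, 20)
  expect_false(tr3$stopped_early)

  # random trajectories agree with a direct replay of the rule
  set.seed(20)
  for (i in 1:50) {
    losses <- round(runif(sample(3:30, 1), 0, 5), 2)
    pat <- sample(1:5, 1)
    got <- early_stop_trace(losses, pat)
    best <- Inf; beste <- 0; wait <- 0; stopat <- length(losses); early <- FALSE
    for (e in seq_along(losses)) {
      if (losses[e] < best) { best <- losses[e]; beste <- e; wait <- 0 }
      else {
        wait <- wait + 1
        if (wait >= pat) { stopat <- e; early <- TRUE; break }
      }
    }
    expect_equal(got$best_epoch, beste)
    expect_equal(got$stop_epoch, stopat)
    expect_equal(got$stopped_early, early)
  }
})

test_that("training histories satisfy the early-stop invariants in a real fit", {
  ds <- generate_dataset(40, c(1, 6), rgb_params_48(), seed = 2)
  split <- seq_split(ds$samples, 24, 8, 8)
  m <- build_model(tiny_cfg(), seed = 0)
  cfg <- training_config(learning_rate = 1e-3, max_epochs = 8,
                         early_stop_patience_epochs = 3, seed = 1)
  res <- fit_counter(m, split, ds$samples, cfg)
  h <- res$history
  expect_equal(h$best_epoch, which.min(h$val_loss))
  if (h$stopped_early)
    expect_gte(length(h$val_loss) - h$best_epoch,
               cfg$early_stop_patience_epochs)
  # restored weights reproduce the best recorded validation loss
  val <- ds$samples[match(split$validation,
                          sapply(ds$samples, `[[`, "sample_id"))]
  raw <- predict_count(res$model, val)$raw_count
  truth <- vapply(val, `[[`, integer(1), "leaf_count")
  expect_equal(mean((raw - truth)^2), min(h$val_loss), tolerance = 1e-8)
})

test_that("training is deterministic under a fixed seed", {
  ds <- generate_dataset(30, c(1, 6), rgb_params_48(), seed = 4)
  split <- seq_split(ds$samples, 18, 6, 6)
  cfg <- training_config(learning_rate = 1e-3, max_epochs = 3, seed = 7)
  r1 <- fit_counter(build_model(tiny_cfg(), seed = 5), split, ds$samples, cfg)
  r2 <- fit_counter(build_model(tiny_cfg(), seed = 5), split, ds$samples, cfg)
  expect_identical(r1$history, r2$history)
  ns <- asNamespace("leafcounter")
  expect_identical(ns$get_weights(r1$model), ns$get_weights(r2$model))
})

test_that("head-only fitting of constant-label data converges to the label", {
  # all samples identical with label k: the MSE-optimal constant is k
  k <- 6L
  s <- generate_plant(rgb_params_48(n_leaves = k), seed = 1)
  samples <- lapply(1:12, function(i) {
    s$sample_id <- sprintf("c%02d", i)
    s
  })
  split <- seq_split(samples, 8, 2, 2)
  m <- build_model(tiny_cfg(), seed = 2)
  cfg <- training_config(learning_rate = 5e-2, l2_lambda = 0,
                         max_epochs = 60, early_stop_patience_epochs = 60,
                         augmentation = NULL, seed = 0,
                         finetune_mode = "head_only")
  res <- fit_counter(m, split, samples, cfg)
  raw <- predict_count(res$model, samples[1:2])$raw_count
  expect_lt(max(abs(raw - k)), 0.5)
})

test_that("stronger L2 never enlarges the regularized layer at convergence", {
  ds <- generate_dataset(20, c(1, 8), rgb_params_48(), seed = 9)
  split <- seq_split(ds$samples, 12, 4, 4)
  norms <- vapply(c(0, 0.05, 0.5), function(lam) {
    m <- build_model(tiny_cfg(), seed = 3)
    cfg <- training_config(learning_rate = 1e-2, l2_lambda = lam,
                           max_epochs = 25, early_stop_patience_epochs = 25,
                           augmentation = NULL, seed = 1,
                           finetune_mode = "head_only")
    res <- fit_counter(m, split, ds$samples, cfg)
    sqrt(sum(res$model$regressor$hidden$W^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("fit validates its inputs", {
  ds <- generate_dataset(10, c(1, 4), rgb_params_48(), seed = 0)
  ids <- sapply(ds$samples, `[[`, "sample_id")
  m <- build_model(tiny_cfg(), seed = 0)
  cfg <- training_config(max_epochs = 1)
  expect_error(
    fit_counter(m, make_split(character(0), ids[1:2], ids[3:4]),
                ds$samples, cfg),
    "insufficient-data")
  expect_error(
    fit_counter(m, make_split(ids[1:4], character(0), ids[5:6]),
                ds$samples, cfg),
    "config error")
  expect_error(training_config(learning_rate = 0), "invalid-config")
  expect_error(training_config(early_stop_patience_epochs = 0),
               "invalid-config")
})

test_that("cross-validation produces per-fold reports of the protocol size", {
  ds <- generate_dataset(32, c(1, 6), rgb_params_48(), seed = 6)
  cfg <- training_config(learning_rate = 1e-3, max_epochs = 2, seed = 0)
  res <- crossvalidate(ds$samples, c(0.5, 0.25, 0.25), n_folds = 2,
                       model_cfg = tiny_cfg(), train_cfg = cfg)
  expect_length(res$folds, 2)
  for (f in res$folds) expect_equal(f$n, 8)
  expect_s3_class(res$mean, "metrics_report")
  expect_equal(res$mean$mse,
               mean(vapply(res$folds, `[[`, numeric(1), "mse")),
               tolerance = 1e-12)
  # a rerun under the same master seed reproduces the reports
  res2 <- crossvalidate(ds$samples, c(0.5, 0.25, 0.25), n_folds = 2,
                        model_cfg = tiny_cfg(), train_cfg = cfg)
  expect_equal(res, res2)
})

test_that("fine-tuning with zero images is a no-op on the weights", {
  ds <- generate_dataset(16, c(1, 6), rgb_params_48(), seed = 8)
  m <- build_model(tiny_cfg(), seed = 1)
  cfg <- training_config(max_epochs = 2, seed = 3)
  res <- finetune(m, ds$samples, 0, cfg)
  ns <- asNamespace("leafcounter")
  expect_identical(ns$get_weights(res$model), ns$get_weights(m))
  expect_s3_class(res$report, "metrics_report")
  expect_null(res$history)
})

test_that("the progressive protocol fine-tunes independent copies", {
  ds <- generate_dataset(24, c(1, 6), rgb_params_48(), seed = 12)
  m <- build_model(tiny_cfg(), seed = 2)
  cfg <- training_config(learning_rate = 1e-3, max_epochs = 2, seed = 5)
  res <- finetune(m, ds$samples, c(2, 4), cfg)
  expect_length(res, 2)
  ns <- asNamespace("leafcounter")
  # the pretrained model itself is untouched
  expect_identical(ns$get_weights(m),
                   ns$get_weights(build_model(tiny_cfg(), seed = 2)))
  for (r in res) expect_s3_class(r$report, "metrics_report")
  expect_error(finetune(m, ds$samples, 1000, cfg), "insufficient-data")
})
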