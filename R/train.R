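#' Training configuration
#'
#' Hyperparameters of the counting-network training protocol: MSE loss
#' between raw (unrounded) predictions and integer ground truth, L2
#' regularization (constant `l2_lambda`, default 0.02) on the regressor
#' hidden layer's weights (the last fully connected layer before the
#' output), adaptive-moment gradient descent at `learning_rate` (default
#' 0.0001), geometric augmentation of the training partition only, and
#' early stopping once the validation error has not improved for
#' `early_stop_patience_epochs` consecutive epochs (default 10), with
#' best-epoch weights restored.
#'
#' @param learning_rate Optimizer step size (> 0).
#' @param l2_lambda L2 constant on the regressor hidden layer (>= 0).
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on training epochs.
#' @param early_stop_patience_epochs Non-improving epochs tolerated
#'   before stopping (>= 1).
#' @param augmentation An [augment_ranges()], or `NULL` to disable.
#' @param seed Integer seed governing shuffling and augmentation.
#' @param finetune_mode `"full"` updates all layers; `"head_only"`
#'   freezes the branches and updates the regressor only.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4,
                            l2_lambda = 0.02,
                            batch_size = 16L,
                            max_epochs = 60L,
                            early_stop_patience_epochs = 10L,
                            augmentation = augment_ranges(),
                            seed = 0L,
                            finetune_mode = c("full", "head_only")) {
  finetune_mode <- match.arg(finetune_mode)
  if (learning_rate <= 0) stop("invalid-config: learning_rate must be > 0")
  if (l2_lambda < 0) stop("invalid-config: l2_lambda must be >= 0")
  if (early_stop_patience_epochs < 1)
    stop("invalid-config: patience must be >= 1")
  structure(list(learning_rate = learning_rate, l2_lambda = l2_lambda,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience_epochs =
                   as.integer(early_stop_patience_epochs),
                 augmentation = augmentation,
                 seed = as.integer(seed),
                 finetune_mode = finetune_mode),
            class = "training_config")
}

#' Early-stopping decision on a validation-loss trajectory
#'
#' Pure replay of the stopping rule used during training: the best epoch
#' is the first attaining the minimum validation loss; training stops at
#' the first epoch whose distance from the incumbent best reaches
#' `patience` non-improving epochs.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Non-improving epochs tolerated (>= 1).
#' @return List with `best_epoch`, `stop_epoch`, `stopped_early`.
#' @export
early_stop_trace <- function(val_losses, patience = 10L) {
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  stop_epoch <- length(val_losses)
  stopped_early <- FALSE
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        stop_epoch <- e
        stopped_early <- TRUE
        break
      }
    }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch,
       stopped_early = stopped_early)
}

## Raw (unrounded) predictions for a list of samples.
predict_raw <- function(model, samples) {
  predict_count(model, samples)$raw_count
}

#' Fit the counting network
#'
#' Trains `model` in place on the training partition of `split`,
#' monitoring MSE on the validation partition for early stopping. The
#' returned model carries the best-epoch weights. The optimized loss is
#' `mean((raw - truth)^2) + l2_lambda * sum(W_hidden^2)`; the validation
#' loss is the pure MSE. Augmentation applies to training samples only.
#' With a fixed `cfg$seed` the run is deterministic.
#'
#' @param model A `counting_model` from [build_model()].
#' @param split A `dataset_split`.
#' @param samples List of labeled `multimodal_sample` covering the split.
#' @param cfg A [training_config()].
#' @param verbose Print one log line per epoch.
#' @return List with `model` (trained, best weights restored) and
#'   `history` (class `training_history`: per-epoch losses, `best_epoch`,
#'   `stopped_early`).
#' @export
fit_counter <- function(model, split, samples, cfg = training_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "counting_model"),
            inherits(split, "dataset_split"),
            inherits(cfg, "training_config"))
  sid <- vapply(samples, `[[`, character(1), "sample_id")
  names(samples) <- sid
  if (length(split$train) == 0)
    stop("insufficient-data: empty training partition")
  if (length(split$validation) == 0)
    stop("config error: early stopping requires a validation partition")
  missing <- setdiff(c(split$train, split$validation), sid)
  if (length(missing))
    stop("missing-data: split references unknown ids: ",
         paste(utils::head(missing, 3), collapse = ", "))
  ## strip masks from working copies; they are not needed for training
  train_samples <- lapply(samples[split$train], function(s) {
    s$masks <- NULL
    s
  })
  val_samples <- samples[split$validation]
  val_truth <- vapply(val_samples, `[[`, integer(1), "leaf_count")
  mods <- model$config$modalities
  chans <- model$config$input_channels_per_modality
  head_only <- cfg$finetune_mode == "head_only"
  trainable <- if (head_only)
    list(model$regressor$hidden, model$regressor$act, model$regressor$out)
  else model_layers(model)

  hist_train <- numeric(0)
  hist_val <- numeric(0)
  improved <- logical(0)
  best <- Inf
  best_epoch <- 0L
  best_weights <- NULL
  wait <- 0L
  stopped_early <- FALSE
  step <- 0L

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(seq_along(train_samples))
      aug_seeds <- sample.int(.Machine$integer.max, length(ord))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      epoch_loss <- 0
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        bs <- lapply(seq_along(b), function(j) {
          s <- train_samples[[b[j]]]
          if (is.null(cfg$augmentation)) s
          else augment_sample(s, cfg$augmentation, seed = aug_seeds[b[j]])
        })
        y <- vapply(bs, `[[`, integer(1), "leaf_count")
        xlist <- lapply(stats::setNames(mods, mods), function(m)
          stack_modality(bs, m, chans[[m]]))
        fwd <- model_forward_train(model, xlist, branch_training = !head_only)
        err <- fwd$raw - y
        whid <- model$regressor$hidden$W
        loss <- mean(err^2) + cfg$l2_lambda * sum(whid^2)
        epoch_loss <- epoch_loss + loss
        draw <- 2 * err / length(err)
        model_backward_train(model, fwd, draw, head_only = head_only)
        model$regressor$hidden$dW <-
          model$regressor$hidden$dW + 2 * cfg$l2_lambda * whid
        step <- step + 1L
        adam_step(trainable, cfg$learning_rate, step)
        clear_grads(trainable)
      }
      val_raw <- predict_raw(model, val_samples)
      val_loss <- mean((val_raw - val_truth)^2)
      hist_train <- c(hist_train, epoch_loss / length(batches))
      hist_val <- c(hist_val, val_loss)
      imp <- val_loss < best
      improved <- c(improved, imp)
      if (imp) {
        best <- val_loss
        best_epoch <- epoch
        best_weights <- get_weights(model)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch,
                        utils::tail(hist_train, 1), val_loss,
                        if (imp) "  *" else ""))
      if (wait >= cfg$early_stop_patience_epochs) {
        stopped_early <- TRUE
        break
      }
    }
  })
  if (!is.null(best_weights)) set_weights(model, best_weights)
  history <- structure(list(
    train_loss = hist_train,
    val_loss = hist_val,
    improved = improved,
    best_epoch = best_epoch,
    stopped_early = stopped_early
  ), class = "training_history")
  list(model = model, history = history)
}

## Forward with training caches; branch caches only when branches train.
model_forward_train <- function(model, xlist, branch_training = TRUE) {
  feats <- lapply(names(model$branches), function(m)
    seq_forward(branch_layers(model$branches[[m]]), xlist[[m]],
                training = branch_training))
  names(feats) <- names(model$branches)
  fused <- Reduce(pmax, feats)
  routing <- vector("list", length(feats))
  assigned <- fused > Inf  # all-FALSE of fused's shape
  for (b in seq_along(feats)) {
    take <- (feats[[b]] == fused) & !assigned
    routing[[b]] <- take
    assigned <- assigned | take
  }
  h <- model$regressor$hidden$forward(fused, TRUE)
  a <- model$regressor$act$forward(h, TRUE)
  raw <- model$regressor$out$forward(a, TRUE)
  list(raw = as.numeric(raw), routing = routing)
}

model_backward_train <- function(model, fwd, draw, head_only = FALSE) {
  dy <- matrix(draw, ncol = 1)
  da <- model$regressor$out$backward(dy)
  dh <- model$regressor$act$backward(da)
  dfused <- model$regressor$hidden$backward(dh)
  if (!head_only) {
    for (b in seq_along(model$branches)) {
      seq_backward(branch_layers(model$branches[[b]]),
                   dfused * fwd$routing[[b]])
    }
  }
  invisible(NULL)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("training history: %d epoch(s), best epoch %d (val %.4f)%s\n",
              length(x$val_loss), x$best_epoch,
              if (x$best_epoch > 0) x$val_loss[x$best_epoch] else NA,
              if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

#' Cross-validated training and evaluation
#'
#' Runs `n_folds` independent rounds: each fold re-randomizes the
#' train/validation/test split, builds a fresh model, fits it and
#' evaluates on the fold's test partition. The aggregate report is the
#' field-wise mean over folds.
#'
#' @param samples List of labeled `multimodal_sample`.
#' @param fractions Split fractions `c(train, validation, test)`.
#' @param n_folds Number of folds (>= 1).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [training_config()]; fold `k` derives its seed as
#'   `seed + k`.
#' @param verbose Log epochs.
#' @return List with `folds` (per-fold `metrics_report`), `mean`
#'   (aggregate report) and `histories`.
#' @export
crossvalidate <- function(samples, fractions = c(0.5, 0.25, 0.25),
                          n_folds = 4L, model_cfg = model_config(),
                          train_cfg = training_config(), verbose = FALSE) {
  if (n_folds < 1) stop("invalid-config: n_folds must be >= 1")
  splits <- split_dataset(samples, fractions, n_folds = n_folds,
                          seed = train_cfg$seed)
  reports <- vector("list", n_folds)
  histories <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    model <- build_model(model_cfg, seed = train_cfg$seed + k)
    cfg_k <- train_cfg
    cfg_k$seed <- train_cfg$seed + k
    res <- fit_counter(model, splits[[k]], samples, cfg_k, verbose = verbose)
    reports[[k]] <- evaluate_model(res$model, samples, splits[[k]]$test)
    histories[[k]] <- res$history
  }
  list(folds = reports, mean = mean_metrics(reports), histories = histories)
}

#' Fine-tune a pre-trained counting network on a new dataset
#'
#' Starts from a copy of `pretrained` (the original is untouched) and
#' continues training with exactly `n_train_images` training images plus
#' a validation subset, then reports held-out-test metrics. Passing a
#' vector of sizes runs the progressive protocol: each size fine-tunes an
#' independent copy of the same pre-trained weights on a nested training
#' subset. With `n_train_images = 0` the model is returned unchanged.
#'
#' @param pretrained A trained `counting_model`.
#' @param new_samples Labeled samples from the new setting.
#' @param n_train_images Integer (or vector) of training-set sizes.
#' @param cfg A [training_config()]; `finetune_mode` selects full-network
#'   or head-only updates.
#' @param split Optional explicit `dataset_split` (e.g. a per-plant
#'   split); its training partition is subsampled to `n_train_images`.
#'   By default a random split with 25% validation and 25% test is drawn
#'   under `cfg$seed`.
#' @return For scalar `n_train_images`, a list with `model`, `report`,
#'   `history`; for a vector, a list of such lists (one per size).
#' @export
finetune <- function(pretrained, new_samples, n_train_images,
                     cfg = training_config(), split = NULL) {
  if (length(n_train_images) > 1) {
    return(lapply(n_train_images, function(n)
      finetune(pretrained, new_samples, n, cfg, split)))
  }
  n <- as.integer(n_train_images)
  ids <- vapply(new_samples, `[[`, character(1), "sample_id")
  if (is.null(split)) {
    nall <- length(new_samples)
    nval <- max(1L, round(0.25 * nall))
    ntest <- max(1L, round(0.25 * nall))
    if (n > nall - nval - ntest)
      stop("insufficient-data: ", n, " training images requested, only ",
           nall - nval - ntest, " available")
    split <- withr::with_seed(cfg$seed, {
      perm <- sample(ids)
      make_split(train = perm[seq_len(nall - nval - ntest)],
                 validation = perm[nall - nval - ntest + seq_len(nval)],
                 test = perm[nall - ntest + seq_len(ntest)])
    })
  }
  if (n > length(split$train))
    stop("insufficient-data: ", n, " training images requested, only ",
         length(split$train), " available")
  model <- clone_model(pretrained)
  if (n == 0) {
    report <- evaluate_model(model, new_samples, split$test)
    return(list(model = model, report = report, history = NULL))
  }
  sub <- make_split(train = split$train[seq_len(n)],
                    validation = split$validation,
                    test = split$test)
  res <- fit_counter(model, sub, new_samples, cfg)
  report <- evaluate_model(res$model, new_samples, split$test)
  list(model = res$model, report = report, history = res$history)
}
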