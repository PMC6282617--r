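#' Architecture description for the counting network
#'
#' Describes the multi-input counting network: one independent
#' residual-convolutional branch per imaging modality, each ending in a
#' fully connected feature layer of `branch_feature_dim` rectified units,
#' an element-wise maximum fusion layer, and a non-linear regressor with a
#' `regressor_hidden_dim`-unit hidden layer feeding a single output neuron
#' that predicts the (real-valued) leaf count.
#'
#' @param modalities Character vector of modality tags, a subset of
#'   `c("rgb", "nir", "fmp")`, in branch order.
#' @param backbone `"tiny_resnet"` (three residual stages, desk-scale) or
#'   `"resnet50"` (full 50-layer residual backbone; minimum input
#'   200x200 pixels).
#' @param branch_feature_dim Width of the per-branch feature layer
#'   (default 1024). All branches share this width; fusion requires it.
#' @param regressor_hidden_dim Width of the regressor hidden layer
#'   (default 512).
#' @param use_pretrained_backbone If `TRUE`, requests externally
#'   pre-trained backbone weights. No source of such weights is bundled,
#'   so building with this flag raises an error; branches are otherwise
#'   randomly initialized.
#' @param weight_decay_lambda L2 regularization constant applied during
#'   training to the regressor hidden layer's weights (default 0.02).
#' @param input_channels_per_modality Named integer vector mapping each
#'   modality to its input channel count. Defaults to 3 for `rgb` and 1
#'   for single-sensor modalities.
#' @return An object of class `model_config`.
#' @export
model_config <- function(modalities = "rgb",
                         backbone = c("tiny_resnet", "resnet50"),
                         branch_feature_dim = 1024L,
                         regressor_hidden_dim = 512L,
                         use_pretrained_backbone = FALSE,
                         weight_decay_lambda = 0.02,
                         input_channels_per_modality = NULL) {
  backbone <- match.arg(backbone)
  modalities <- as.character(modalities)
  if (length(modalities) == 0)
    stop("invalid-config: at least one modality is required")
  if (anyDuplicated(modalities))
    stop("invalid-config: modality tags must be unique")
  unknown <- setdiff(modalities, c("rgb", "nir", "fmp"))
  if (length(unknown))
    stop("unsupported-modality: ", paste(unknown, collapse = ", "))
  if (branch_feature_dim < 1 || regressor_hidden_dim < 1)
    stop("invalid-config: layer widths must be positive")
  if (weight_decay_lambda < 0)
    stop("invalid-config: weight_decay_lambda must be nonnegative")
  if (is.null(input_channels_per_modality)) {
    input_channels_per_modality <-
      vapply(modalities, function(m) if (m == "rgb") 3L else 1L, integer(1))
  }
  if (!all(modalities %in% names(input_channels_per_modality)))
    stop("invalid-config: input_channels_per_modality must cover all modalities")
  structure(list(
    modalities = modalities,
    backbone = backbone,
    branch_feature_dim = as.integer(branch_feature_dim),
    regressor_hidden_dim = as.integer(regressor_hidden_dim),
    use_pretrained_backbone = isTRUE(use_pretrained_backbone),
    weight_decay_lambda = weight_decay_lambda,
    input_channels_per_modality = input_channels_per_modality
  ), class = "model_config")
}

## Minimum admissible input side per backbone. ResNet50's bound follows
## its aggressive stem downsampling; the tiny backbone needs just enough
## pixels to survive its three stride-2 stages.
backbone_min_input <- function(backbone) {
  switch(backbone, resnet50 = 200L, tiny_resnet = 32L)
}

tiny_resnet_branch <- function(cin, feature_dim) {
  stage <- function(cin, cout) {
    nn_residual(
      main = list(nn_conv(3L, cin, cout, stride = 2L), nn_relu(),
                  nn_conv(3L, cout, cout, stride = 1L)),
      skip = list(nn_conv(1L, cin, cout, stride = 2L, pad = 0L))
    )
  }
  list(
    stem = list(nn_conv(3L, cin, 16L, stride = 2L), nn_relu()),
    blocks = list(stage(16L, 32L), stage(32L, 64L), stage(64L, 64L)),
    head = list(nn_gap(), nn_dense(64L, feature_dim), nn_relu())
  )
}

resnet50_branch <- function(cin, feature_dim) {
  bottleneck <- function(cin, width, stride, project) {
    skip <- if (project)
      list(nn_conv(1L, cin, 4L * width, stride = stride, pad = 0L),
           nn_channel_affine(4L * width))
    else list()
    nn_residual(
      main = list(
        nn_conv(1L, cin, width, stride = 1L, pad = 0L),
        nn_channel_affine(width), nn_relu(),
        nn_conv(3L, width, width, stride = stride),
        nn_channel_affine(width), nn_relu(),
        nn_conv(1L, width, 4L * width, stride = 1L, pad = 0L),
        nn_channel_affine(4L * width)
      ),
      skip = skip
    )
  }
  widths <- c(64L, 128L, 256L, 512L)
  depths <- c(3L, 4L, 6L, 3L)
  blocks <- list()
  cprev <- 64L
  for (s in seq_along(widths)) {
    for (b in seq_len(depths[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      project <- b == 1L
      blocks <- c(blocks, list(bottleneck(cprev, widths[s], stride, project)))
      cprev <- 4L * widths[s]
    }
  }
  list(
    stem = list(nn_conv(7L, cin, 64L, stride = 2L, pad = 3L),
                nn_channel_affine(64L), nn_relu(),
                nn_maxpool(3L, 2L, pad = 1L)),
    blocks = blocks,
    head = list(nn_gap(), nn_dense(2048L, feature_dim), nn_relu())
  )
}

#' Build the multi-branch counting network
#'
#' Realizes a [model_config()]: one independent (unshared) branch per
#' modality, parameter-free element-wise maximum fusion, and the
#' regression head. Initialization is deterministic under `seed`.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `counting_model`.
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$use_pretrained_backbone)
    stop("pretrained backbone weights are not bundled with this package; ",
         "build with use_pretrained_backbone = FALSE")
  model <- new.env(parent = emptyenv())
  model$config <- cfg
  withr::with_seed(as.integer(seed), {
    model$branches <- lapply(stats::setNames(cfg$modalities, cfg$modalities),
      function(m) {
        cin <- cfg$input_channels_per_modality[[m]]
        switch(cfg$backbone,
               tiny_resnet = tiny_resnet_branch(cin, cfg$branch_feature_dim),
               resnet50 = resnet50_branch(cin, cfg$branch_feature_dim))
      })
    model$regressor <- list(
      hidden = nn_dense(cfg$branch_feature_dim, cfg$regressor_hidden_dim),
      act = nn_relu(),
      out = nn_dense(cfg$regressor_hidden_dim, 1L)
    )
  })
  class(model) <- "counting_model"
  model
}

#' @export
print.counting_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(layer_weights(model_layers(x)),
                   function(w) sum(lengths(w)), numeric(1)))
  cat("Multi-modal leaf counting network\n")
  cat("  backbone:", cfg$backbone, "\n")
  cat("  branches:", paste(cfg$modalities, collapse = ", "),
      sprintf("(feature dim %d, unshared weights)\n", cfg$branch_feature_dim))
  cat("  fusion:   element-wise maximum\n")
  cat(sprintf("  regressor: %d ReLU units -> 1 output neuron\n",
              cfg$regressor_hidden_dim))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  invisible(x)
}

branch_layers <- function(branch) c(branch$stem, branch$blocks, branch$head)

model_layers <- function(model) {
  c(unlist(lapply(model$branches, branch_layers), recursive = FALSE),
    list(model$regressor$hidden, model$regressor$act, model$regressor$out))
}

get_weights <- function(model) layer_weights(model_layers(model))

set_weights <- function(model, weights) {
  set_layer_weights(model_layers(model), weights)
  invisible(model)
}

clone_model <- function(model) {
  m2 <- build_model(model$config, seed = 0L)
  set_weights(m2, get_weights(model))
  m2
}

#' Forward pass of one modality branch
#'
#' Runs a single preprocessed image through its modality branch and
#' returns the fixed-length feature vector. The feature length equals
#' `branch_feature_dim` regardless of admissible input size, realized by
#' global average pooling ahead of the feature layer; all entries are
#' nonnegative (ReLU).
#'
#' @param model A [build_model()] network.
#' @param modality Modality tag of the branch to run.
#' @param image Preprocessed image (H x W matrix or H x W x C array,
#'   values in \[0, 1\]).
#' @return Numeric vector of length `branch_feature_dim`.
#' @export
branch_forward <- function(model, modality, image) {
  if (!modality %in% names(model$branches))
    stop("modality-mismatch: model has no '", modality, "' branch")
  x <- image_to_batch(image, model$config$input_channels_per_modality[[modality]])
  minside <- backbone_min_input(model$config$backbone)
  if (min(dim(x)[1:2]) < minside)
    stop(sprintf("input-too-small: %s backbone requires at least %d x %d pixels",
                 model$config$backbone, minside, minside))
  f <- seq_forward(branch_layers(model$branches[[modality]]), x, training = FALSE)
  as.numeric(f)
}

## Coerce one image to an (H, W, C, 1) batch, replicating a single
## channel to the branch's expected channel count when needed.
image_to_batch <- function(image, channels) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L) stop("invalid-input: image must be 2-D or 3-D")
  if (d[3] == 1L && channels > 1L)
    image <- array(rep(image, channels), c(d[1], d[2], channels))
  else if (d[3] != channels)
    stop(sprintf("invalid-input: expected %d channel(s), got %d", channels, d[3]))
  array(image, c(d[1], d[2], channels, 1L))
}

## Stack one modality of several samples into an (H, W, C, N) batch.
stack_modality <- function(samples, modality, channels) {
  imgs <- lapply(samples, function(s) {
    if (is.null(s$images[[modality]]))
      stop("modality-mismatch: sample ", s$sample_id,
           " lacks modality '", modality, "'")
    image_to_batch(s$images[[modality]], channels)
  })
  d <- dim(imgs[[1]])
  for (im in imgs) {
    if (!identical(dim(im), d))
      stop("invalid-input: all samples must share per-modality image size")
  }
  array(unlist(imgs, use.names = FALSE), c(d[1], d[2], d[3], length(imgs)))
}

#' Element-wise maximum feature fusion
#'
#' Combines per-branch feature vectors into one by taking, at every
#' feature index, the maximum across branches. The operation is
#' idempotent, commutative and monotone, and reduces to the identity for
#' a single branch.
#'
#' @param features List of numeric vectors (or single-row matrices) of
#'   equal length, one per branch.
#' @return Numeric vector of the same length.
#' @export
fuse_features <- function(features) {
  if (!is.list(features) || length(features) == 0)
    stop("no-modalities: feature list must be nonempty")
  features <- lapply(features, as.numeric)
  n <- unique(lengths(features))
  if (length(n) != 1)
    stop("incompatible-features: feature vectors differ in length")
  Reduce(pmax, features)
}

#' Round a raw count prediction to a reportable integer
#'
#' The network regresses a real-valued count; rounding happens only at
#' test time. Ties round half away from zero and negative raw outputs
#' clamp to zero.
#'
#' @param raw Numeric vector of raw count predictions.
#' @return Integer vector of nonnegative rounded counts.
#' @export
round_count <- function(raw) {
  r <- sign(raw) * floor(abs(raw) + 0.5)
  as.integer(pmax(r, 0))
}

#' Predict leaf counts for samples
#'
#' Runs the full network (branches, fusion, regressor) in inference mode.
#' By default the sample must provide exactly the modalities the model
#' was built with; with `allow_subset = TRUE` the element-wise maximum is
#' taken over the branches whose modality is present (well-defined for
#' any nonempty subset — an extension beyond the reference protocol).
#'
#' @param model A trained (or freshly built) `counting_model`.
#' @param samples A `multimodal_sample` or list of them.
#' @param allow_subset Permit samples that carry only a subset of the
#'   model's modalities.
#' @param batch_size Samples per forward batch.
#' @return A data.frame with columns `sample_id`, `raw_count`,
#'   `rounded_count`, in input order.
#' @export
predict_count <- function(model, samples, allow_subset = FALSE,
                          batch_size = 32L) {
  if (inherits(samples, "multimodal_sample")) samples <- list(samples)
  need <- model$config$modalities
  have <- Reduce(intersect, lapply(samples, function(s) names(s$images)))
  use <- if (allow_subset) intersect(need, have) else need
  missing <- setdiff(need, have)
  if (!allow_subset && length(missing))
    stop("modality-mismatch: sample(s) lack modality ",
         paste(missing, collapse = ", "),
         " (use allow_subset = TRUE to fuse over the available subset)")
  if (length(use) == 0)
    stop("no-modalities: no model modality present in the samples")
  raws <- numeric(length(samples))
  idx <- split(seq_along(samples), ceiling(seq_along(samples) / batch_size))
  for (ii in idx) {
    xlist <- lapply(stats::setNames(use, use), function(m)
      stack_modality(samples[ii], m,
                     model$config$input_channels_per_modality[[m]]))
    feats <- lapply(use, function(m)
      seq_forward(branch_layers(model$branches[[m]]), xlist[[m]], FALSE))
    fused <- Reduce(pmax, feats)
    h <- model$regressor$hidden$forward(fused, FALSE)
    a <- model$regressor$act$forward(h, FALSE)
    raws[ii] <- as.numeric(model$regressor$out$forward(a, FALSE))
  }
  data.frame(
    sample_id = vapply(samples, function(s) s$sample_id, character(1)),
    raw_count = raws,
    rounded_count = round_count(raws),
    stringsAsFactors = FALSE
  )
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding a format version, the
#' [model_config()] and all weights.
#'
#' @param model A `counting_model`.
#' @param path File path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored `counting_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = 1L,
               config = model$config,
               weights = get_weights(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format_version, 1L))
    stop("unsupported checkpoint format version: ", ck$format_version)
  model <- build_model(ck$config, seed = 0L)
  set_weights(model, ck$weights)
  model
}
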