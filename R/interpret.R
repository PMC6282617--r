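#' Occlusion-based count saliency map
#'
#' Measures which image regions contribute to the predicted count: a
#' square patch slides over one modality of the sample (the other
#' modalities untouched), the patch is replaced by a fill value, and the
#' map records the raw predicted count with the patch occluded minus the
#' unoccluded baseline. For a well-behaved counter, only plant-bearing
#' regions should move the count.
#'
#' @param model A trained `counting_model`.
#' @param sample A `multimodal_sample` carrying all model modalities.
#' @param modality Modality to occlude.
#' @param patch_size_px Side of the occluding square, pixels.
#' @param stride_px Stride between patch positions.
#' @param fill `"mean"` (per-channel image mean) or `"gray"` (0.5).
#' @param batch_size Occluded variants evaluated per forward pass.
#' @return An object of class `saliency_map`: `delta` (grid of signed
#'   count changes, rows = vertical patch positions), `patch_size_px`,
#'   `stride_px`, `modality`, `baseline_raw`.
#' @export
occlusion_count_map <- function(model, sample, modality = NULL,
                                patch_size_px = 8L, stride_px = 8L,
                                fill = c("mean", "gray"),
                                batch_size = 64L) {
  fill <- match.arg(fill)
  if (is.null(modality)) modality <- model$config$modalities[1]
  img <- sample$images[[modality]]
  if (is.null(img))
    stop("modality-mismatch: sample lacks modality '", modality, "'")
  d <- dim(img)
  if (patch_size_px > min(d[1:2]))
    stop("invalid-patch: patch exceeds the image side")
  nh <- (d[1] - patch_size_px) %/% stride_px + 1L
  nw <- (d[2] - patch_size_px) %/% stride_px + 1L
  baseline <- predict_count(model, sample)$raw_count
  fillval <- if (fill == "gray") 0.5 else {
    if (length(d) == 3) apply(img, 3, mean) else mean(img)
  }
  occlude <- function(ih, iw) {
    rows <- (ih - 1L) * stride_px + seq_len(patch_size_px)
    cols <- (iw - 1L) * stride_px + seq_len(patch_size_px)
    im <- img
    if (length(d) == 3) {
      for (ch in seq_len(d[3]))
        im[rows, cols, ch] <- if (length(fillval) > 1) fillval[ch] else fillval
    } else {
      im[rows, cols] <- fillval
    }
    s <- sample
    s$images[[modality]] <- im
    s
  }
  pos <- expand.grid(ih = seq_len(nh), iw = seq_len(nw))
  variants <- lapply(seq_len(nrow(pos)), function(i) {
    s <- occlude(pos$ih[i], pos$iw[i])
    s$sample_id <- sprintf("%s_occ%04d", sample$sample_id, i)
    s
  })
  raw <- predict_count(model, variants, batch_size = batch_size)$raw_count
  delta <- matrix(raw - baseline, nh, nw)
  structure(list(delta = delta, patch_size_px = as.integer(patch_size_px),
                 stride_px = as.integer(stride_px), modality = modality,
                 baseline_raw = baseline),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(
    "occlusion saliency map: %d x %d grid (patch %d, stride %d, %s)\n",
    nrow(x$delta), ncol(x$delta), x$patch_size_px, x$stride_px, x$modality))
  cat(sprintf("  baseline raw count %.2f; |delta| range [%.3f, %.3f]\n",
              x$baseline_raw, min(abs(x$delta)), max(abs(x$delta))))
  invisible(x)
}

#' Contrast saliency over plant versus background patches
#'
#' Summarizes a saliency map against the sample's binary plant mask:
#' mean absolute count change for patches overlapping the plant versus
#' patches of pure background.
#'
#' @param smap A [occlusion_count_map()] result.
#' @param mask Logical plant mask of the occluded modality (e.g.
#'   `sample$masks[[modality]]`).
#' @return List with `plant_mean_abs_delta`, `background_mean_abs_delta`
#'   and `n_plant` / `n_background` patch counts.
#' @export
saliency_mask_contrast <- function(smap, mask) {
  nh <- nrow(smap$delta); nw <- ncol(smap$delta)
  onplant <- matrix(FALSE, nh, nw)
  for (ih in seq_len(nh)) {
    rows <- (ih - 1L) * smap$stride_px + seq_len(smap$patch_size_px)
    for (iw in seq_len(nw)) {
      cols <- (iw - 1L) * smap$stride_px + seq_len(smap$patch_size_px)
      onplant[ih, iw] <- any(mask[rows, cols])
    }
  }
  list(plant_mean_abs_delta = mean(abs(smap$delta[onplant])),
       background_mean_abs_delta = mean(abs(smap$delta[!onplant])),
       n_plant = sum(onplant), n_background = sum(!onplant))
}

#' Mean activation map of the first residual block
#'
#' Runs one modality branch up to its first residual block and returns
#' the mean activation across feature channels — a coarse view of where
#' that branch "looks". Values are nonnegative (post-ReLU); the spatial
#' size is the block's output resolution.
#'
#' @param model A `counting_model`.
#' @param sample A `multimodal_sample`.
#' @param modality Branch to inspect.
#' @return Numeric matrix (H' x W') of mean activations.
#' @export
branch_activation_map <- function(model, sample, modality) {
  if (!modality %in% names(model$branches))
    stop("modality-mismatch: model has no '", modality, "' branch")
  img <- sample$images[[modality]]
  if (is.null(img))
    stop("modality-mismatch: sample lacks modality '", modality, "'")
  x <- image_to_batch(img, model$config$input_channels_per_modality[[modality]])
  br <- model$branches[[modality]]
  x <- seq_forward(br$stem, x, training = FALSE)
  x <- br$blocks[[1]]$forward(x, training = FALSE)
  d <- dim(x)
  matrix(rowMeans(matrix(x, nrow = d[1] * d[2])), d[1], d[2])
}
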