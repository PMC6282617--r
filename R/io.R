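#' Preprocessing configuration
#'
#' Controls the standardization applied to every image before it enters
#' the network: per-channel histogram normalization followed by resizing
#' to a square of `target_size_px` (default 320). In the multi-source
#' regime, a modality whose native side falls below
#' `min_backbone_input_px` (default 200, the ResNet50 minimum) is
#' instead upsampled to `upsample_target_px` (default 240) while the
#' other modalities are left on the standard rule.
#'
#' @param target_size_px Square output side for the standard rule.
#' @param min_backbone_input_px Minimum admissible native side before
#'   the small-source rule kicks in (multi-source regime only).
#' @param upsample_target_px Output side under the small-source rule.
#' @param normalization `"histogram_equalization"` (per channel) or
#'   `"none"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size_px = 320L,
                              min_backbone_input_px = 200L,
                              upsample_target_px = 240L,
                              normalization = c("histogram_equalization",
                                                "none")) {
  normalization <- match.arg(normalization)
  if (target_size_px < min_backbone_input_px)
    stop("invalid-config: target_size_px must be >= min_backbone_input_px")
  if (upsample_target_px < min_backbone_input_px)
    stop("invalid-config: upsample_target_px must be >= min_backbone_input_px")
  structure(list(target_size_px = as.integer(target_size_px),
                 min_backbone_input_px = as.integer(min_backbone_input_px),
                 upsample_target_px = as.integer(upsample_target_px),
                 normalization = normalization),
            class = "preprocess_config")
}

#' Preprocess one image
#'
#' Applies per-channel histogram equalization (if configured) and resizes
#' to the square side mandated by `cfg` (see [preprocess_config()]).
#' Inputs with values above 1 are assumed 8-bit and rescaled by 1/255.
#' Constant images pass through equalization unchanged.
#'
#' @param image 2-D matrix or H x W x C array.
#' @param modality Modality tag (informational; the small-source rule is
#'   driven by the image's own native size).
#' @param cfg A [preprocess_config()].
#' @param multi_source Set `TRUE` when modalities from heterogeneous
#'   sensors are combined, enabling the small-source upsampling rule.
#' @return Array (or matrix) with values in \[0, 1\], square of the
#'   configured side.
#' @export
preprocess_image <- function(image, modality = "rgb",
                             cfg = preprocess_config(),
                             multi_source = FALSE) {
  if (length(image) == 0 || any(dim(image)[1:2] == 0))
    stop("invalid-input: zero-sized image")
  img <- image
  if (max(img) > 1) img <- img / 255
  img <- pmin(pmax(img, 0), 1)
  was_matrix <- is.matrix(img)
  if (was_matrix) img <- array(img, c(dim(img), 1L))
  if (cfg$normalization == "histogram_equalization") {
    for (ch in seq_len(dim(img)[3])) {
      x <- img[, , ch]
      if (diff(range(x)) > 0)
        img[, , ch] <- suppressWarnings(
          EBImage::equalize(x, range = c(0, 1), levels = 256))
    }
  }
  native <- min(dim(img)[1:2])
  side <- if (multi_source && native < cfg$min_backbone_input_px)
    cfg$upsample_target_px else cfg$target_size_px
  if (!identical(dim(img)[1:2], c(side, side)))
    img <- EBImage::resize(img, w = side, h = side)
  img <- pmin(pmax(img, 0), 1)
  if (was_matrix) img <- img[, , 1]
  img
}

#' Augmentation ranges
#'
#' Geometric training-time augmentation: random rotation, zoom and shift.
#' Defaults reflect top-view rosette imagery (full rotational symmetry,
#' mild zoom, shifts up to 10% of the image side).
#'
#' @param rotation_deg `c(min, max)` rotation range in degrees.
#' @param zoom `c(min, max)` isotropic scale range; must be positive.
#' @param shift_frac `c(min, max)` per-axis shift range as a fraction of
#'   the image side.
#' @return An object of class `augment_ranges`.
#' @export
augment_ranges <- function(rotation_deg = c(0, 360),
                           zoom = c(0.9, 1.1),
                           shift_frac = c(-0.1, 0.1)) {
  if (any(zoom <= 0)) stop("invalid-range: zoom range must be positive")
  if (diff(rotation_deg) < 0 || diff(zoom) < 0 || diff(shift_frac) < 0)
    stop("invalid-range: ranges must satisfy min <= max")
  structure(list(rotation_deg = rotation_deg, zoom = zoom,
                 shift_frac = shift_frac), class = "augment_ranges")
}

## Apply one affine (rotate about center, zoom, shift) to a 2-D/3-D image.
apply_affine <- function(img, angle_deg, zoom, shift_frac) {
  d <- dim(img)
  th <- angle_deg * pi / 180
  R <- zoom * rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  ctr <- d[1:2] / 2
  off <- ctr - ctr %*% R + shift_frac * d[1:2]
  m <- rbind(R, off)
  out <- EBImage::affine(img, m)
  out <- pmin(pmax(as.array(out), 0), 1)
  if (is.matrix(img)) out <- matrix(out, d[1], d[2])
  out
}

#' Augment a sample with a random geometric transform
#'
#' Draws one rotation/zoom/shift triple and applies the *same* transform
#' parameters to every modality of the sample (shifts scale with each
#' modality's own side). The leaf count is unchanged; output is
#' deterministic given `seed`.
#'
#' @param sample A `multimodal_sample` (preprocessed).
#' @param ranges An [augment_ranges()].
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @return The transformed `multimodal_sample`.
#' @export
augment_sample <- function(sample, ranges = augment_ranges(), seed = 0L) {
  stopifnot(inherits(ranges, "augment_ranges"))
  draw <- function() {
    list(angle = stats::runif(1, ranges$rotation_deg[1], ranges$rotation_deg[2]),
         zoom = stats::runif(1, ranges$zoom[1], ranges$zoom[2]),
         shift = stats::runif(2, ranges$shift_frac[1], ranges$shift_frac[2]))
  }
  tr <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  identity_tr <- tr$angle == 0 && tr$zoom == 1 && all(tr$shift == 0)
  if (!identity_tr) {
    for (m in names(sample$images))
      sample$images[[m]] <- apply_affine(sample$images[[m]], tr$angle,
                                         tr$zoom, tr$shift)
    if (!is.null(sample$masks)) {
      for (m in names(sample$masks))
        sample$masks[[m]] <- apply_affine(sample$masks[[m]] * 1, tr$angle,
                                          tr$zoom, tr$shift) > 0.5
    }
  }
  sample
}

#' Write a counting dataset to disk
#'
#' Layout: `<root>/<modality>/<sample_id>.png` plus `<root>/counts.csv`
#' with header `sample_id,plant_id,frame,leaf_count`.
#'
#' @param samples List of `multimodal_sample` (or the list returned by
#'   [generate_dataset()]).
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(samples, root) {
  if (!is.null(samples$samples)) samples <- samples$samples
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    for (m in names(s$images)) {
      dir.create(file.path(root, m), showWarnings = FALSE)
      png::writePNG(s$images[[m]], file.path(root, m,
                                             paste0(s$sample_id, ".png")))
    }
  }
  counts <- data.frame(
    sample_id = vapply(samples, `[[`, character(1), "sample_id"),
    plant_id = vapply(samples, `[[`, character(1), "plant_id"),
    frame = vapply(samples, function(s) as.integer(s$timestamp), integer(1)),
    leaf_count = vapply(samples, `[[`, integer(1), "leaf_count"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(counts, file.path(root, "counts.csv"), row.names = FALSE)
  invisible(root)
}

#' Load a counting dataset from disk
#'
#' Reads the layout written by [write_dataset()] (one image subdirectory
#' per modality, ids matched to file stems case-sensitively) and attaches
#' ground-truth counts.
#'
#' @param root_dir Dataset root directory.
#' @param modalities Modalities to load.
#' @param counts_table Path to the ground-truth CSV (default
#'   `<root>/counts.csv`); must contain `sample_id` and integer
#'   `leaf_count` columns, optionally `plant_id` and `frame`.
#' @return List of `multimodal_sample`.
#' @export
load_counting_dataset <- function(root_dir, modalities = "rgb",
                                  counts_table = file.path(root_dir,
                                                           "counts.csv")) {
  if (!file.exists(counts_table))
    stop("missing-data: counts table not found: ", counts_table)
  tab <- utils::read.csv(counts_table, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "leaf_count") %in% names(tab)))
    stop("parse error: counts table needs sample_id and leaf_count columns")
  cnt <- suppressWarnings(as.numeric(tab$leaf_count))
  if (any(is.na(cnt)) || any(cnt != as.integer(cnt)))
    stop("parse error: leaf_count must be integer, offending value(s): ",
         paste(utils::head(tab$leaf_count[is.na(cnt) | cnt != floor(cnt)], 3),
               collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    id <- as.character(tab$sample_id[i])
    images <- list()
    for (m in modalities) {
      f <- file.path(root_dir, m, paste0(id, ".png"))
      if (!file.exists(f))
        stop("missing-data: no image for id '", id, "' in modality '", m,
             "' (expected ", f, ")")
      img <- png::readPNG(f)
      images[[m]] <- img
    }
    structure(list(
      sample_id = id,
      plant_id = if ("plant_id" %in% names(tab))
        as.character(tab$plant_id[i]) else id,
      timestamp = if ("frame" %in% names(tab))
        as.integer(tab$frame[i]) else NA_integer_,
      images = images,
      leaf_count = as.integer(cnt[i]),
      masks = NULL
    ), class = "multimodal_sample")
  })
}

#' Construct a train/validation/test split directly from id lists
#'
#' @param train,validation,test Character vectors of sample ids; must be
#'   pairwise disjoint.
#' @param fold_index,n_folds Bookkeeping for cross-validation folds.
#' @return An object of class `dataset_split`.
#' @export
make_split <- function(train, validation, test, fold_index = 1L,
                       n_folds = 1L) {
  all_ids <- c(train, validation, test)
  if (anyDuplicated(all_ids))
    stop("invalid-split: partitions must be pairwise disjoint")
  structure(list(train = train, validation = validation, test = test,
                 fold_index = as.integer(fold_index),
                 n_folds = as.integer(n_folds)),
            class = "dataset_split")
}

#' Random train/validation/test splits
#'
#' Produces `n_folds` independently re-randomized splits (each fold
#' reshuffles all samples, matching the cross-validation protocol of
#' re-splitting at random rather than rotating disjoint folds).
#' Partition sizes are the rounded fractions of the dataset size. With
#' `by_plant = TRUE` all frames of one plant stay in one partition.
#'
#' @param samples List of `multimodal_sample`.
#' @param fractions `c(train, validation, test)` positive fractions
#'   summing to at most 1.
#' @param n_folds Number of independent splits.
#' @param seed Integer seed (fold `k` uses `seed + k`).
#' @param by_plant Keep plants intact across partitions.
#' @return List of `dataset_split`, length `n_folds`.
#' @export
split_dataset <- function(samples, fractions = c(0.5, 0.25, 0.25),
                          n_folds = 1L, seed = 0L, by_plant = FALSE) {
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("invalid-fractions: need three positive fractions")
  if (sum(fractions) > 1 + 1e-9)
    stop("invalid-fractions: fractions must sum to at most 1")
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  plants <- vapply(samples, `[[`, character(1), "plant_id")
  n <- length(ids)
  sizes <- round(fractions * n)
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
  lapply(seq_len(n_folds), function(k) {
    withr::with_seed(as.integer(seed) + k, {
      if (by_plant) {
        up <- unique(plants)
        if (length(up) < 3)
          stop("infeasible-split: fewer plants than partitions")
        up <- sample(up)
        parts <- list(character(0), character(0), character(0))
        target <- sizes
        for (p in up) {
          pid <- ids[plants == p]
          deficit <- target - lengths(parts)
          j <- which.max(deficit)
          parts[[j]] <- c(parts[[j]], pid)
        }
        make_split(parts[[1]], parts[[2]], parts[[3]], k, n_folds)
      } else {
        perm <- sample(ids)
        make_split(perm[seq_len(sizes[1])],
                   perm[sizes[1] + seq_len(sizes[2])],
                   perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
                   k, n_folds)
      }
    })
  })
}
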