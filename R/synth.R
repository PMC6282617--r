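## Synthetic multi-modal rosette image generator.
##
## Plants are rendered as rosettes of ellipse-shaped leaf blades (plus a
## short petiole segment) placed around a jittered center at successive
## golden-angle offsets, with sizes increasing with leaf age rank. Each
## modality renders the same plant geometry with its own contrast model,
## raster size and noise, so images share labels but not pixels —
## mirroring multi-sensor rigs whose resolution and alignment differ.
## Ground truth is exact by construction.

REF_SIDE <- 64  # leaf geometry is specified in pixels of a 64-px canvas

#' Parameters of the synthetic rosette generator
#'
#' @param n_leaves Integer leaf count (>= 0); the ground truth.
#' @param divergence_angle_deg Angle between successive leaves (default
#'   137.5, the golden angle typical of rosette phyllotaxis).
#' @param leaf_length_px Length range `c(min, max)` of the blade across
#'   leaf age ranks, in reference pixels (64-px canvas); the oldest leaf
#'   gets `max`, the youngest `min`.
#' @param leaf_width_px Blade width range `c(min, max)` matched to the
#'   same age ranks.
#' @param center_jitter_px Uniform jitter of the plant center, reference
#'   pixels.
#' @param occlusion_factor Fraction in \[0, 1\] pulling blades toward the
#'   center; 0 keeps blades pairwise disjoint (for modest leaf counts),
#'   1 piles them on the center.
#' @param background_kind Background style: `soil_texture` (textured
#'   brown), `dark`, or `tray` (light gray).
#' @param noise_sd Named per-modality additive Gaussian noise SD in
#'   intensity units. Defaults: rgb 0.02, nir 0.01, fmp 0.05.
#' @param image_size_per_modality Named list modality -> `c(H, W)`; its
#'   names define which modalities are rendered. Defaults to rgb 64x64,
#'   nir 80x80, fmp 48x48 (deliberately unequal).
#' @param clutter Fraction in \[0, 1\] controlling greenish background
#'   blobs in the rgb rendering that can be confused with blades (the
#'   single-modality ambiguity knob; nir stays clean).
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(n_leaves = 5L,
                         divergence_angle_deg = 137.5,
                         leaf_length_px = c(8, 24),
                         leaf_width_px = c(4, 11),
                         center_jitter_px = 3,
                         occlusion_factor = 0.2,
                         background_kind = c("soil_texture", "dark", "tray"),
                         noise_sd = c(rgb = 0.02, nir = 0.01, fmp = 0.05),
                         image_size_per_modality = list(rgb = c(64, 64),
                                                        nir = c(80, 80),
                                                        fmp = c(48, 48)),
                         clutter = 0.15) {
  background_kind <- match.arg(background_kind)
  if (length(n_leaves) != 1 || is.na(n_leaves) || n_leaves < 0 ||
      n_leaves != as.integer(n_leaves))
    stop("invalid-parameter: n_leaves must be a single nonnegative integer")
  if (occlusion_factor < 0 || occlusion_factor > 1)
    stop("invalid-parameter: occlusion_factor must lie in [0, 1]")
  if (any(leaf_length_px <= 0) || any(leaf_width_px <= 0) ||
      diff(leaf_length_px) < 0 || diff(leaf_width_px) < 0)
    stop("invalid-parameter: leaf size ranges must be positive and ordered")
  mods <- names(image_size_per_modality)
  unknown <- setdiff(mods, c("rgb", "nir", "fmp"))
  if (length(unknown))
    stop("unsupported-modality: ", paste(unknown, collapse = ", "))
  if (length(mods) == 0)
    stop("invalid-parameter: at least one modality must be requested")
  for (sz in image_size_per_modality)
    if (length(sz) != 2 || any(sz <= 0))
      stop("invalid-parameter: image sizes must be positive (H, W) pairs")
  if (clutter < 0 || clutter > 1)
    stop("invalid-parameter: clutter must lie in [0, 1]")
  structure(list(
    n_leaves = as.integer(n_leaves),
    divergence_angle_deg = divergence_angle_deg,
    leaf_length_px = leaf_length_px,
    leaf_width_px = leaf_width_px,
    center_jitter_px = center_jitter_px,
    occlusion_factor = occlusion_factor,
    background_kind = background_kind,
    noise_sd = noise_sd,
    image_size_per_modality = image_size_per_modality,
    clutter = clutter
  ), class = "plant_params")
}

## Smooth low-frequency texture in [0, 1]: coarse uniform grid upsampled.
smooth_noise <- function(h, w, coarse = 8L) {
  g <- matrix(stats::runif(coarse * coarse), coarse, coarse)
  as.matrix(EBImage::resize(g, w = h, h = w))
}

## Leaf geometry for one plant, in reference-pixel coordinates centered
## on the canvas midpoint. Oldest leaf first (rank 1 = largest).
make_geometry <- function(params) {
  n <- params$n_leaves
  center <- REF_SIDE / 2 +
    stats::runif(2, -params$center_jitter_px, params$center_jitter_px)
  base_angle <- stats::runif(1, 0, 360)
  leaves <- list()
  if (n > 0) {
    rank_frac <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
    len <- params$leaf_length_px[2] -
      diff(params$leaf_length_px) * rank_frac
    wid <- params$leaf_width_px[2] - diff(params$leaf_width_px) * rank_frac
    for (k in seq_len(n)) {
      leaves[[k]] <- list(
        angle = (base_angle + (k - 1) * params$divergence_angle_deg +
                   stats::rnorm(1, 0, 4)) %% 360,
        len = len[k] * stats::runif(1, 0.9, 1.1),
        wid = wid[k] * stats::runif(1, 0.9, 1.1),
        shade = stats::runif(1, -0.06, 0.06)
      )
    }
  }
  ## Blade inner tip: a small gap at occlusion 0, pushed through the
  ## center as the occlusion factor grows.
  gap0 <- 4
  f <- params$occlusion_factor
  for (k in seq_along(leaves))
    leaves[[k]]$r_tip <- gap0 - f * (gap0 + 0.35 * leaves[[k]]$len)
  nblobs <- stats::rpois(1, params$clutter * 10)
  blobs <- replicate(nblobs, list(
    x = stats::runif(1, 2, REF_SIDE - 2),
    y = stats::runif(1, 2, REF_SIDE - 2),
    a = stats::runif(1, 2, 7),
    b = stats::runif(1, 1.5, 5),
    angle = stats::runif(1, 0, 360),
    g = stats::runif(1, 0.30, 0.50)
  ), simplify = FALSE)
  misreg <- lapply(stats::setNames(nm = names(params$image_size_per_modality)),
                   function(m) stats::runif(2, -1.5, 1.5))
  list(center = center, leaves = leaves, blobs = blobs, misreg = misreg)
}

## Rasterize an ellipse (center cx, cy; semi-axes a, b; orientation deg)
## onto the logical canvas described by coordinate matrices X, Y.
ellipse_mask <- function(X, Y, cx, cy, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  u <- cos(th) * (X - cx) + sin(th) * (Y - cy)
  v <- -sin(th) * (X - cx) + cos(th) * (Y - cy)
  (u / a)^2 + (v / b)^2 <= 1
}

## Render one modality raster; returns list(img, mask).
render_modality <- function(geom, modality, size, params) {
  H <- size[1]; W <- size[2]
  ## coordinate grids in reference pixels (rows = y, cols = x)
  xs <- (seq_len(W) - 0.5) * REF_SIDE / W
  ys <- (seq_len(H) - 0.5) * REF_SIDE / H
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  ctr <- geom$center + geom$misreg[[modality]]
  mask <- matrix(FALSE, H, W)
  leaf_id <- matrix(0L, H, W)
  ## At occlusion 0 the generator *guarantees* one connected component
  ## per leaf: a blade colliding with already-placed leaves is pushed
  ## outward along its own axis until clear (checked against a 1-pixel
  ## dilation of the placed mask, so components cannot even touch
  ## diagonally). With occlusion > 0 overlap is intended and no pushing
  ## happens.
  enforce_disjoint <- params$occlusion_factor == 0 && length(geom$leaves) > 1
  placed_dil <- matrix(FALSE, H, W)
  brush <- EBImage::makeBrush(3, shape = "box")
  leaf_mask_at <- function(lf, push) {
    th <- lf$angle * pi / 180
    rtip <- lf$r_tip + push
    bc <- ctr + c(cos(th), sin(th)) * (rtip + lf$len / 2)
    m <- ellipse_mask(X, Y, bc[1], bc[2], lf$len / 2, lf$wid / 2, lf$angle)
    ## short petiole segment toward the center, kept off the center point
    r0 <- max(rtip - 3, 2.5)
    if (rtip > r0) {
      u <- cos(th) * (X - ctr[1]) + sin(th) * (Y - ctr[2])
      v <- -sin(th) * (X - ctr[1]) + cos(th) * (Y - ctr[2])
      m <- m | (u >= r0 & u <= rtip + 0.5 & abs(v) <= 0.7)
    }
    m
  }
  for (k in seq_along(geom$leaves)) {
    lf <- geom$leaves[[k]]
    push <- 0
    repeat {
      m <- leaf_mask_at(lf, push)
      if (!enforce_disjoint || push >= 40 || !any(m & placed_dil)) break
      push <- push + 1
    }
    leaf_id[m] <- k  # younger (smaller) leaves drawn on top
    mask <- mask | m
    if (enforce_disjoint)
      placed_dil <- placed_dil | (EBImage::dilate(m * 1, brush) > 0.5)
  }
  shades <- vapply(geom$leaves, `[[`, numeric(1), "shade")
  img <- switch(modality,
    rgb = {
      bg <- switch(params$background_kind,
        soil_texture = {
          tex <- 0.7 + 0.6 * smooth_noise(H, W)
          base <- c(0.36, 0.28, 0.20)
          array(c(base[1] * tex, base[2] * tex, base[3] * tex), c(H, W, 3))
        },
        dark = array(0.06 + 0.02 * smooth_noise(H, W), c(H, W, 3)),
        tray = {
          tex <- 0.9 + 0.2 * smooth_noise(H, W)
          array(c(0.55 * tex, 0.55 * tex, 0.58 * tex), c(H, W, 3))
        })
      for (bl in geom$blobs) {
        bm <- ellipse_mask(X, Y, bl$x, bl$y, bl$a, bl$b, bl$angle)
        bm <- bm & !mask
        r <- bg[, , 1]; g <- bg[, , 2]; b <- bg[, , 3]
        r[bm] <- 0.22; g[bm] <- bl$g; b[bm] <- 0.16
        bg <- array(c(r, g, b), c(H, W, 3))
      }
      r <- bg[, , 1]; g <- bg[, , 2]; b <- bg[, , 3]
      on <- leaf_id > 0
      r[on] <- 0.18
      g[on] <- 0.55 + shades[leaf_id[on]]
      b[on] <- 0.14
      array(c(r, g, b), c(H, W, 3))
    },
    nir = {
      im <- 0.08 + 0.04 * smooth_noise(H, W)
      on <- leaf_id > 0
      im[on] <- 0.78 + shades[leaf_id[on]]
      im
    },
    fmp = {
      im <- matrix(0.02, H, W)
      on <- leaf_id > 0
      im[on] <- 0.65 + shades[leaf_id[on]]
      im
    })
  sd <- params$noise_sd[[modality]]
  if (is.null(sd) || is.na(sd)) sd <- 0.02
  if (sd > 0) img <- img + stats::rnorm(length(img), 0, sd)
  img <- pmin(pmax(img, 0), 1)
  if (length(dim(img)) == 0) dim(img) <- c(H, W)
  list(img = img, mask = mask)
}

render_sample <- function(geom, params, sample_id, plant_id, timestamp,
                          leaf_count) {
  images <- list()
  masks <- list()
  for (m in names(params$image_size_per_modality)) {
    r <- render_modality(geom, m, params$image_size_per_modality[[m]], params)
    images[[m]] <- r$img
    masks[[m]] <- r$mask
  }
  structure(list(
    sample_id = sample_id,
    plant_id = plant_id,
    timestamp = timestamp,
    images = images,
    leaf_count = as.integer(leaf_count),
    masks = masks
  ), class = "multimodal_sample")
}

#' Generate one synthetic multi-modal plant observation
#'
#' Renders a rosette with exactly `params$n_leaves` leaves in every
#' modality named in `params$image_size_per_modality`. The returned
#' sample also carries the per-modality binary plant masks (`$masks`),
#' used by saliency checks.
#'
#' @param params A [plant_params()].
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   output. `NULL` draws from the current RNG stream.
#' @return A `multimodal_sample`: `sample_id`, `plant_id`, `timestamp`,
#'   `images` (named list of arrays in \[0, 1\]), `leaf_count`, `masks`.
#' @export
generate_plant <- function(params, seed = 0L) {
  stopifnot(inherits(params, "plant_params"))
  gen <- function() {
    geom <- make_geometry(params)
    render_sample(geom, params, sample_id = "s0001", plant_id = "s0001",
                  timestamp = NA_integer_, leaf_count = params$n_leaves)
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Generate an annotated synthetic counting dataset
#'
#' Leaf counts are drawn uniformly from `leaf_range`. Randomness flows
#' from a per-sample substream (`seed + i` for sample `i`), so a dataset
#' is stable as a prefix under changes of `n_samples`.
#'
#' @param n_samples Number of plants (>= 1).
#' @param leaf_range `c(min, max)` inclusive integer range of counts.
#' @param params_template [plant_params()] template; its `n_leaves` is
#'   overridden per sample.
#' @param seed Integer master seed.
#' @return List with `samples` (list of `multimodal_sample`) and `counts`
#'   (data.frame: sample_id, plant_id, frame, leaf_count).
#' @export
generate_dataset <- function(n_samples, leaf_range = c(1, 12),
                             params_template = plant_params(),
                             seed = 0L) {
  if (n_samples < 1) stop("invalid-parameter: n_samples must be >= 1")
  if (length(leaf_range) != 2 || leaf_range[1] > leaf_range[2])
    stop("invalid-range: leaf_range must satisfy min <= max")
  if (leaf_range[1] < 0)
    stop("invalid-range: leaf counts must be nonnegative")
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    samples[[i]] <- withr::with_seed(as.integer(seed) + i, {
      k <- leaf_range[1] + sample.int(leaf_range[2] - leaf_range[1] + 1L, 1) - 1L
      p <- params_template
      p$n_leaves <- as.integer(k)
      geom <- make_geometry(p)
      id <- sprintf("s%04d", i)
      render_sample(geom, p, sample_id = id, plant_id = id,
                    timestamp = NA_integer_, leaf_count = k)
    })
  }
  counts <- data.frame(
    sample_id = vapply(samples, `[[`, character(1), "sample_id"),
    plant_id = vapply(samples, `[[`, character(1), "plant_id"),
    frame = NA_integer_,
    leaf_count = vapply(samples, `[[`, integer(1), "leaf_count"),
    stringsAsFactors = FALSE
  )
  list(samples = samples, counts = counts)
}

#' Generate a growth time series for one plant
#'
#' Emulates time-lapse acquisitions of a single growing rosette: leaf
#' positions persist across frames, blades grow with age, counts follow
#' the (non-decreasing) schedule exactly, and timestamps increase.
#'
#' @param plant_id Identifier attached to every frame.
#' @param n_frames Number of frames; must equal `length(count_schedule)`.
#' @param count_schedule Non-decreasing integer leaf counts per frame.
#' @param params_template [plant_params()] template.
#' @param seed Integer seed.
#' @return List of `multimodal_sample`, one per frame.
#' @export
generate_growth_series <- function(plant_id, n_frames, count_schedule,
                                   params_template = plant_params(),
                                   seed = 0L) {
  if (length(count_schedule) != n_frames)
    stop("invalid-schedule: count_schedule length must equal n_frames")
  if (n_frames < 1) stop("invalid-schedule: n_frames must be >= 1")
  if (any(diff(count_schedule) < 0))
    stop("invalid-schedule: leaf counts must be non-decreasing over time")
  if (any(count_schedule < 0))
    stop("invalid-schedule: leaf counts must be nonnegative")
  withr::with_seed(as.integer(seed), {
    nmax <- max(count_schedule)
    p <- params_template
    p$n_leaves <- as.integer(nmax)
    template <- make_geometry(p)  # mature geometry; frames scale it back
    emerge <- vapply(seq_len(nmax), function(j)
      which(count_schedule >= j)[1], integer(1))
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      k <- count_schedule[t]
      g <- template
      g$leaves <- g$leaves[seq_len(k)]
      if (k > 0) {
        for (j in seq_len(k)) {
          age <- t - emerge[j]
          grow <- 1 - 0.75 * exp(-age / 4)
          g$leaves[[j]]$len <- template$leaves[[j]]$len * grow
          g$leaves[[j]]$wid <- template$leaves[[j]]$wid * grow
        }
      }
      pt <- p
      pt$n_leaves <- as.integer(k)
      frames[[t]] <- render_sample(
        g, pt, sample_id = sprintf("%s_f%03d", plant_id, t),
        plant_id = plant_id, timestamp = t, leaf_count = k)
    }
    frames
  })
}

#' @export
print.multimodal_sample <- function(x, ...) {
  sizes <- vapply(x$images, function(im)
    paste(dim(im)[1:2], collapse = "x"), character(1))
  cat(sprintf("multimodal_sample %s (plant %s%s): %s leaves\n",
              x$sample_id, x$plant_id,
              if (is.na(x$timestamp)) "" else paste0(", frame ", x$timestamp),
              if (is.na(x$leaf_count)) "?" else x$leaf_count))
  cat("  modalities:",
      paste(sprintf("%s [%s]", names(x$images), sizes), collapse = ", "), "\n")
  invisible(x)
}
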