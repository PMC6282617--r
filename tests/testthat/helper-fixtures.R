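# Shared fixtures. Everything is generated in code at test time; the
# heavier trained models are cached in an environment so that several
# test files can reuse one training run.

fix_cache <- new.env()

cached <- function(key, expr) {
  if (is.null(fix_cache[[key]])) fix_cache[[key]] <- force(expr)
  fix_cache[[key]]
}

rgb_params_64 <- function(...) {
  plant_params(image_size_per_modality = list(rgb = c(64, 64)), ...)
}

rgb_params_48 <- function(...) {
  plant_params(image_size_per_modality = list(rgb = c(48, 48)), ...)
}

# Small model config for fast unit tests (not the study configuration).
tiny_cfg <- function(modalities = "rgb", feature_dim = 32L, hidden = 16L) {
  model_config(modalities, backbone = "tiny_resnet",
               branch_feature_dim = feature_dim,
               regressor_hidden_dim = hidden)
}

seq_split <- function(samples, n_train, n_val, n_test) {
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  make_split(ids[seq_len(n_train)],
             ids[n_train + seq_len(n_val)],
             ids[n_train + n_val + seq_len(n_test)])
}

# ---- study-scale fixtures shared by the acceptance checks ------------

# Full-protocol single-modality study: 64x64 rgb rosettes, counts 1-12,
# 300 train / 100 validation / 100 test, seed 0.
count_recovery_run <- function() {
  cached("count_recovery", {
    ds <- generate_dataset(500, c(1, 12), rgb_params_64(), seed = 0)
    split <- seq_split(ds$samples, 300, 100, 100)
    model <- build_model(model_config("rgb"), seed = 0)
    cfg <- training_config(learning_rate = 1e-3, max_epochs = 20, seed = 0)
    res <- fit_counter(model, split, ds$samples, cfg)
    list(samples = ds$samples, split = split, model = res$model,
         history = res$history,
         report = evaluate_model(res$model, ds$samples, split$test))
  })
}

# Reduced-scale single-modality runs used for multi-seed trend checks:
# 48x48 rosettes, counts 1-10, 150 train / 40 val / 40 test, 12 epochs.
small_recovery_run <- function(seed) {
  cached(paste0("small_recovery_", seed), {
    ds <- generate_dataset(230, c(1, 10), rgb_params_48(), seed = seed)
    split <- seq_split(ds$samples, 150, 40, 40)
    model <- build_model(model_config("rgb"), seed = seed)
    cfg <- training_config(learning_rate = 1e-3, max_epochs = 12, seed = seed)
    res <- fit_counter(model, split, ds$samples, cfg)
    list(samples = ds$samples, split = split, model = res$model)
  })
}

# Multi-modal generator with modality-specific ambiguity: cluttered rgb,
# clean nir, noisy fmp, all 48x48.
ambiguous_params <- function() {
  plant_params(
    image_size_per_modality = list(rgb = c(48, 48), nir = c(48, 48),
                                   fmp = c(48, 48)),
    clutter = 0.5,
    noise_sd = c(rgb = 0.03, nir = 0.01, fmp = 0.15)
  )
}

# Dataset style pair for fine-tuning / agglomeration trend checks.
style_a_params <- function() {
  rgb_params_48(background_kind = "soil_texture", clutter = 0.4)
}

style_b_params <- function() {
  rgb_params_48(background_kind = "tray", clutter = 0,
                leaf_width_px = c(3, 8))
}

trend_train_cfg <- function(seed, max_epochs = 12L) {
  training_config(learning_rate = 1e-3, max_epochs = max_epochs, seed = seed)
}
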