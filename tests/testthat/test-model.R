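test_that("model building is deterministic and honors configured widths", {
  cfg <- model_config("rgb", branch_feature_dim = 1024,
                      regressor_hidden_dim = 512)
  ns <- asNamespace("leafcounter")
  m1 <- build_model(cfg, seed = 0)
  m2 <- build_model(cfg, seed = 0)
  expect_identical(ns$get_weights(m1), ns$get_weights(m2))
  m3 <- build_model(cfg, seed = 1)
  expect_false(identical(ns$get_weights(m1), ns$get_weights(m3)))

  expect_equal(dim(m1$regressor$hidden$W), c(1024, 512))
  expect_equal(dim(m1$regressor$out$W), c(512, 1))
  f <- branch_forward(m1, "rgb", array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_length(f, 1024)
})

test_that("branches are independent: perturbing one leaves others unchanged", {
  cfg <- tiny_cfg(c("rgb", "nir", "fmp"))
  m <- build_model(cfg, seed = 2)
  img <- matrix(runif(48 * 48), 48, 48)
  before <- branch_forward(m, "nir", img)
  # scramble the rgb branch
  m$branches$rgb$stem[[1]]$W <- m$branches$rgb$stem[[1]]$W * 5 + 1
  expect_identical(branch_forward(m, "nir", img), before)
  expect_length(m$branches, 3)
})

test_that("branch features are nonnegative and size-invariant in length", {
  m <- build_model(tiny_cfg(), seed = 0)
  f240 <- branch_forward(m, "rgb", array(runif(240 * 240 * 3),
                                         c(240, 240, 3)))
  f320 <- branch_forward(m, "rgb", array(runif(320 * 320 * 3),
                                         c(320, 320, 3)))
  expect_length(f240, length(f320))
  expect_gte(min(f240), 0)
  expect_gte(min(f320), 0)
  expect_error(branch_forward(m, "rgb", array(runif(16 * 16 * 3),
                                              c(16, 16, 3))),
               "input-too-small")
  expect_error(branch_forward(m, "fmp", matrix(0.5, 64, 64)),
               "modality-mismatch")
})

test_that("the 50-layer backbone enforces its 200-pixel minimum input", {
  cfg <- model_config("rgb", backbone = "resnet50",
                      branch_feature_dim = 64, regressor_hidden_dim = 32)
  m <- build_model(cfg, seed = 0)
  expect_error(branch_forward(m, "rgb", array(runif(150 * 150 * 3),
                                              c(150, 150, 3))),
               "input-too-small.*200")
  f <- branch_forward(m, "rgb", array(runif(208 * 208 * 3), c(208, 208, 3)))
  expect_length(f, 64)
  expect_gte(min(f), 0)
  expect_error(build_model(model_config("rgb", backbone = "resnet50",
                                        use_pretrained_backbone = TRUE)),
               "pretrained")
})

test_that("element-wise maximum fusion obeys its algebra", {
  expect_equal(fuse_features(list(c(0.2, 0.5))), c(0.2, 0.5))
  expect_equal(fuse_features(list(c(1, 2), c(2, 1))), c(2, 2))
  v <- runif(16)
  expect_equal(fuse_features(list(v, v)), v)
  expect_error(fuse_features(list(c(1, 2), c(1, 2, 3))),
               "incompatible-features")
  expect_error(fuse_features(list()), "no-modalities")
})

test_that("counts round half away from zero and clamp at zero", {
  expect_identical(round_count(c(3.4, 3.5, -0.3, 2.5, 0.49)),
                   c(3L, 4L, 0L, 3L, 0L))
})

test_that("prediction is strict about modalities unless opted out", {
  m <- build_model(tiny_cfg(c("rgb", "nir")), seed = 1)
  s <- generate_plant(plant_params(
    n_leaves = 4,
    image_size_per_modality = list(rgb = c(48, 48))), seed = 0)
  expect_error(predict_count(m, s), "modality-mismatch")
  p <- predict_count(m, s, allow_subset = TRUE)
  expect_equal(nrow(p), 1)
  expect_true(p$rounded_count >= 0)
})

test_that("batch prediction preserves order and matches single prediction", {
  m <- build_model(tiny_cfg(), seed = 3)
  ds <- generate_dataset(7, c(1, 8), rgb_params_48(), seed = 5)
  pb <- predict_count(m, ds$samples, batch_size = 3)
  expect_equal(pb$sample_id, vapply(ds$samples, `[[`, character(1),
                                    "sample_id"))
  p1 <- predict_count(m, ds$samples[[4]])
  expect_equal(pb$raw_count[4], p1$raw_count, tolerance = 1e-12)
})

test_that("checkpoints round-trip through save and load", {
  m <- build_model(tiny_cfg(), seed = 6)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  m2 <- load_model(path)
  ns <- asNamespace("leafcounter")
  expect_identical(ns$get_weights(m), ns$get_weights(m2))
  expect_identical(m2$config, m$config)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  expect_equal(branch_forward(m, "rgb", img), branch_forward(m2, "rgb", img))
})
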