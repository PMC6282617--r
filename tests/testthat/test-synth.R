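test_that("ground truth is exact by construction, including the zero case", {
  s0 <- generate_plant(rgb_params_64(n_leaves = 0), seed = 1)
  expect_identical(s0$leaf_count, 0L)
  expect_equal(sum(s0$masks$rgb), 0)

  s5 <- generate_plant(plant_params(n_leaves = 5), seed = 0)
  expect_identical(s5$leaf_count, 5L)
  expect_setequal(names(s5$images), c("rgb", "nir", "fmp"))
  expect_true(all(vapply(s5$images, function(im) all(im >= 0 & im <= 1),
                         logical(1))))
})

test_that("disjoint blades at zero occlusion give one component per leaf", {
  for (n in c(3, 5, 8)) {
    s <- generate_plant(rgb_params_64(n_leaves = n, occlusion_factor = 0,
                                      center_jitter_px = 1),
                        seed = 10 + n)
    lab <- EBImage::bwlabel(s$masks$rgb * 1)
    expect_equal(max(lab), n, info = paste("n_leaves =", n))
  }
})

test_that("identical params and seed reproduce bit-identical samples", {
  p <- plant_params(n_leaves = 7)
  expect_identical(generate_plant(p, seed = 42), generate_plant(p, seed = 42))
  d1 <- generate_dataset(4, c(2, 6), rgb_params_64(), seed = 9)
  d2 <- generate_dataset(4, c(2, 6), rgb_params_64(), seed = 9)
  expect_identical(d1, d2)
})

test_that("datasets are prefix-stable and cover the requested count range", {
  d6 <- generate_dataset(6, c(1, 12), rgb_params_48(), seed = 3)
  d4 <- generate_dataset(4, c(1, 12), rgb_params_48(), seed = 3)
  expect_identical(d6$samples[1:4], d4$samples)

  # empirical tally over a large draw covers every count in the range
  big <- generate_dataset(
    400, c(1, 12),
    plant_params(image_size_per_modality = list(rgb = c(24, 24))),
    seed = 1)
  expect_setequal(sort(unique(big$counts$leaf_count)), 1:12)
  expect_equal(nrow(big$counts), 400)
  expect_true(all(big$counts$leaf_count ==
                    vapply(big$samples, `[[`, integer(1), "leaf_count")))
})

test_that("degenerate leaf range fixes every sample's count", {
  d <- generate_dataset(10, c(3, 3), rgb_params_48(), seed = 0)
  expect_true(all(d$counts$leaf_count == 3L))
})

test_that("parameter validation rejects impossible requests", {
  expect_error(plant_params(n_leaves = -1), "invalid-parameter")
  expect_error(plant_params(occlusion_factor = 1.5), "invalid-parameter")
  expect_error(plant_params(image_size_per_modality = list(depth = c(30, 30))),
               "unsupported-modality")
  expect_error(generate_dataset(0, c(1, 5)), "invalid-parameter")
  expect_error(generate_dataset(5, c(6, 2)), "invalid-range")
})

test_that("growth series follow the schedule with persistent geometry", {
  sched <- c(2, 2, 3, 4)
  fr <- generate_growth_series("p01", 4, sched, rgb_params_48(), seed = 5)
  expect_length(fr, 4)
  expect_equal(vapply(fr, `[[`, integer(1), "leaf_count"), sched)
  expect_equal(vapply(fr, `[[`, integer(1), "timestamp"), 1:4)
  expect_true(all(vapply(fr, `[[`, character(1), "plant_id") == "p01"))
  # leaves persist and grow: plant area is non-decreasing frame to frame
  areas <- vapply(fr, function(s) sum(s$masks$rgb), numeric(1))
  expect_true(all(diff(areas) >= 0))

  expect_error(generate_growth_series("p", 2, c(4, 3)), "invalid-schedule")
  expect_error(generate_growth_series("p", 3, c(1, 2)), "invalid-schedule")
})

test_that("long time-lapse schedules render with non-decreasing counts", {
  # structure of a 10-day, six-frames-per-day acquisition
  sched <- sort(sample(rep(1:8, length.out = 60)))
  fr <- generate_growth_series(
    "k00", 60, sched,
    plant_params(image_size_per_modality = list(rgb = c(32, 32))),
    seed = 2)
  counts <- vapply(fr, `[[`, integer(1), "leaf_count")
  expect_equal(counts, sched)
  expect_true(all(diff(vapply(fr, `[[`, integer(1), "timestamp")) > 0))
})

test_that("modalities render with the intended contrast ordering", {
  s <- generate_plant(plant_params(n_leaves = 8), seed = 4)
  contrast <- function(m) {
    img <- s$images[[m]]
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    mean(img[s$masks[[m]]]) - mean(img[!s$masks[[m]]])
  }
  # nir and fmp separate plant from background strongly; rgb less so
  expect_gt(contrast("nir"), 0.4)
  expect_gt(contrast("fmp"), 0.4)
  expect_lt(abs(contrast("rgb")), contrast("nir"))
  # per-modality sizes deliberately differ
  expect_false(identical(dim(s$images$rgb)[1:2], dim(s$images$nir)[1:2]))
})
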