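test_that("metrics match hand-computed values on a worked example", {
  r <- compute_metrics(c(4, 5, 6), c(3, 5, 7))  # d = 1, 0, -1
  expect_equal(r$dic_mean, 0)
  expect_equal(r$dic_sd, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$abs_dic_mean, 2 / 3, tolerance = 1e-12)
  expect_equal(r$abs_dic_sd, sqrt(2 / 9), tolerance = 1e-12)
  expect_equal(r$mse, 2 / 3, tolerance = 1e-12)
  expect_equal(r$agreement_pct, 100 / 3, tolerance = 1e-12)
  expect_equal(r$within_one_pct, 100)

  perfect <- compute_metrics(c(2, 4, 6), c(2, 4, 6))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$agreement_pct, 100)
  expect_equal(perfect$r_squared, 1)
})

test_that("metrics agree with a brute-force oracle on random vectors", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    truth <- sample(0:30, n, replace = TRUE)
    pred <- pmax(truth + sample(-3:3, n, replace = TRUE), 0)
    got <- compute_metrics(pred, truth)
    want <- naive_metrics(pred, truth)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9, info = f)
    # population-SD convention makes the decomposition exact
    expect_equal(got$mse, got$dic_mean^2 + got$dic_sd^2, tolerance = 1e-9)
  }
})

test_that("shifting all predictions shifts the mean but not the spread", {
  set.seed(11)
  truth <- sample(1:20, 30, replace = TRUE)
  pred <- truth + sample(-2:2, 30, replace = TRUE)
  a <- compute_metrics(pred, truth)
  b <- compute_metrics(pred + 1, truth)
  expect_equal(b$dic_mean, a$dic_mean + 1, tolerance = 1e-12)
  expect_equal(b$dic_sd, a$dic_sd, tolerance = 1e-12)
})

test_that("the coefficient of determination behaves at its anchors", {
  truth <- c(2, 4, 6, 8, 10)
  expect_equal(compute_metrics(truth, truth)$r_squared, 1)
  # constant prediction at the truth mean explains nothing
  expect_equal(compute_metrics(rep(6, 5), truth)$r_squared, 0)
  # shifted predictions are penalized (not mere correlation)
  expect_lt(compute_metrics(truth + 2, truth)$r_squared, 1)
})

test_that("error distributions bin signed errors and report the ±1 band", {
  d <- error_distribution(c(1, 3, 4, 5), c(2, 3, 3, 5))  # errors -1 0 1 0
  expect_equal(unname(d$histogram[c("-1", "0", "1")]), c(1, 2, 1))
  expect_equal(sum(d$histogram), 4)
  expect_equal(d$within_one, 1)

  d2 <- error_distribution(c(0, 3, 5), c(2, 3, 4))  # errors -2 0 1
  expect_equal(d2$within_one, 2 / 3, tolerance = 1e-12)
  expect_error(error_distribution(numeric(0), numeric(0)), "invalid-input")
  expect_error(compute_metrics(1:3, 1:4), "invalid-input")
})

test_that("paired method comparison matches the t-distribution oracle", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 7)
  r <- compare_methods(a, b, paired = TRUE)
  # independent recomputation from first principles
  dif <- a - b
  tref <- mean(dif) / (sd(dif) / sqrt(length(dif)))
  pref <- 2 * pt(-abs(tref), length(dif) - 1)
  expect_equal(r$t, tref, tolerance = 1e-12)
  expect_equal(r$df, length(dif) - 1)
  expect_equal(r$p_value, pref, tolerance = 1e-12)

  # swapping the methods flips the sign of t, p unchanged
  r2 <- compare_methods(b, a, paired = TRUE)
  expect_equal(r2$t, -r$t, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)

  expect_warning(same <- compare_methods(a, a, paired = TRUE),
                 "zero-variance")
  expect_equal(same$p_value, 1)
  expect_error(compare_methods(1:3, 1:4, paired = TRUE), "pairing")
})
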