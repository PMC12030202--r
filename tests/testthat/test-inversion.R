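make_records <- function(n_per_stage = 20, noise_sd = 0, seed = 101) {
  set.seed(seed)
  stages <- rep(c("TR", "JT", "HD", "FL"), each = n_per_stage)
  nni <- runif(length(stages), 0.4, 1.3)
  refl <- simulate_reflectance(nni, noise_sd = noise_sd, seed = seed + 1)
  cbind(data.frame(stage = stages, nni = nni), compute_all_indices(refl))
}

test_that("70/30 split has exact arithmetic and is stratified", {
  d <- make_records(20)
  s <- split_dataset(d, 0.7, seed = 1)
  expect_equal(nrow(s$train), 56)
  expect_equal(nrow(s$test), 24)
  expect_equal(nrow(s$train) + nrow(s$test), 80)
  expect_equal(length(intersect(rownames(s$train), rownames(s$test))), 0)
  # stage proportions preserved
  expect_true(all(table(s$train$stage) == 14))
  expect_true(all(table(s$test$stage) == 6))
})

test_that("split is deterministic and handles boundaries", {
  d <- make_records(5)
  s1 <- split_dataset(d, 0.7, seed = 42)
  s2 <- split_dataset(d, 0.7, seed = 42)
  expect_identical(s1, s2)
  expect_warning(full <- split_dataset(d, 1.0, seed = 1), "empty test")
  expect_equal(nrow(full$test), 0)
  expect_error(split_dataset(d[1:5, ], 0.7), "at least 10")
})

test_that("forest learns a monotone NNI-index relationship", {
  d <- make_records(20, noise_sd = 0)
  s <- split_dataset(d, 0.7, seed = 2)
  m <- fit_nni_rf(s$train, VI_NAMES, spec = inversion_spec(seed = 7))
  pred_tr <- predict(m, s$train)
  expect_gte(evaluate_inversion(pred_tr, s$train$nni)$r2, 0.95)
  # predictions are averages of training responses
  expect_true(all(pred_tr >= m$train_range[1] & pred_tr <= m$train_range[2]))
  pred_te <- predict(m, s$test)
  expect_gte(cor(pred_te, s$test$nni, method = "spearman"), 0.9)
})

test_that("forest fitting is deterministic and respects its contracts", {
  d <- make_records(10)
  s <- split_dataset(d, 0.7, seed = 3)
  m1 <- fit_nni_rf(s$train, VI_NAMES, spec = inversion_spec(seed = 5))
  m2 <- fit_nni_rf(s$train, VI_NAMES, spec = inversion_spec(seed = 5))
  expect_equal(predict(m1, s$test), predict(m2, s$test))

  const <- s$train; const$nni <- 0.9
  mc <- suppressWarnings(fit_nni_rf(const, VI_NAMES))
  expect_equal(predict(mc, s$test), rep(0.9, nrow(s$test)),
               tolerance = 1e-12)

  expect_error(fit_nni_rf(s$train, c("ndvi", "nope")), "nope")
  bad <- s$train; bad$ndvi[1] <- NA
  expect_error(fit_nni_rf(bad, VI_NAMES), "undefined feature")
  expect_error(predict(m1, s$test[, "stage", drop = FALSE]),
               "missing feature")
})

test_that("hyperparameter spec is validated", {
  expect_error(inversion_spec(n_trees = 0), "n_trees")
  expect_error(inversion_spec(max_depth = 0), "max_depth")
  s <- inversion_spec()
  expect_equal(s$n_trees, 100L)
  expect_equal(s$max_depth, 2)
})

test_that("evaluation metrics match their definitions", {
  m <- evaluate_inversion(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$k, 1)

  m2 <- evaluate_inversion(c(1.1, 0.9, 1.1, 0.9), c(1, 1, 1, 1))
  expect_equal(m2$rmse, 0.1, tolerance = 1e-12)

  expect_error(evaluate_inversion(1:3, 1:4), "same length")
})

test_that("RMSE matches a loop-summation oracle and ignores order", {
  set.seed(41)
  pred <- runif(100, 0.5, 1.5)
  meas <- runif(100, 0.5, 1.5)
  m <- evaluate_inversion(pred, meas)
  expect_equal(m$rmse, rmse_oracle(pred, meas), tolerance = 1e-12)
  perm <- sample(100)
  mp <- evaluate_inversion(pred[perm], meas[perm])
  expect_equal(mp$rmse, m$rmse, tolerance = 1e-12)
  expect_equal(mp$r2, m$r2, tolerance = 1e-12)
  expect_equal(mp$k, m$k, tolerance = 1e-12)
  expect_equal(m$k, sum(pred * meas) / sum(meas^2), tolerance = 1e-12)
})
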