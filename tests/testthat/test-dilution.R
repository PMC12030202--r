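test_that("plant N accumulation matches hand arithmetic", {
  expect_equal(plant_n_accumulation(2000, 1.5, 3000, 0.8, 0, 0), 54)
  expect_equal(plant_n_accumulation(1000, 1.0, 0, 0, 0, 0), 10)
  expect_equal(plant_n_accumulation(2000, 0, 3000, 0, 500, 0), 0)
  expect_error(plant_n_accumulation(-1, 1, 0, 0), ">= 0")
  expect_error(plant_n_accumulation(1000, 12, 0, 0), "\\[0, 10\\]")
})

test_that("PNA is additive over organs and degree-1 in dry weights", {
  set.seed(4)
  for (i in 1:20) {
    w <- runif(3, 0, 5000); n <- runif(3, 0, 4)
    total <- plant_n_accumulation(w[1], n[1], w[2], n[2], w[3], n[3])
    parts <- plant_n_accumulation(w[1], n[1], 0, 0, 0, 0) +
      plant_n_accumulation(0, 0, w[2], n[2], 0, 0) +
      plant_n_accumulation(0, 0, 0, 0, w[3], n[3])
    expect_equal(total, parts, tolerance = 1e-12)
    expect_equal(plant_n_accumulation(3 * w[1], n[1], 3 * w[2], n[2],
                                      3 * w[3], n[3]),
                 3 * total, tolerance = 1e-12)
  }
})

test_that("treatment grouping follows the adjacent-rate LSD rule", {
  # DM means 2, 4, 6, 6, 6 with tiny within-group spread: DM stops
  # responding at the third rate, so the first two rates are N-limited
  set.seed(11)
  rates <- rep(c(0, 60, 120, 160, 200), each = 4)
  dm <- rep(c(2, 4, 6, 6, 6), each = 4) + rnorm(20, 0, 0.01)
  nconc <- rep(c(1.0, 1.2, 1.4, 1.6, 1.8), each = 4) + rnorm(20, 0, 0.005)
  cls <- classify_n_status(dm, nconc, rates)
  expect_equal(unname(cls$status),
               c("limited", "limited", rep("non_limited", 3)))
  expect_true(cls$usable)
  expect_true(cls$f_dm > 100)
})

test_that("indistinguishable treatments flag the date as unusable", {
  set.seed(12)
  rates <- rep(c(0, 60, 120, 160, 200), each = 3)
  dm <- 5 + rnorm(15, 0, 0.01)
  nconc <- 1.5 + rnorm(15, 0, 0.01)
  expect_warning(cls <- classify_n_status(dm, nconc, rates),
                 "indistinguishable")
  expect_false(cls$usable)
})

test_that("grouping rejects unreplicated or too-few treatments", {
  expect_error(classify_n_status(1:3, 1:3, c(0, 60, 120)), "replicate")
  expect_error(classify_n_status(1:4, 1:4, rep(c(0, 60), each = 2)),
               "3 treatments")
})

test_that("noise-free generator partition matches plateau membership", {
  cfg <- noisefree_config()
  tr <- simulate_trial(cfg)
  jt <- tr[tr$stage == "JT", ]
  cls <- classify_n_status(jt$shoot_dm, jt$shoot_n, jt$n_rate)
  truth <- ifelse(tapply(jt$nni_true, jt$n_rate, mean) <
                    cfg$plateau_true$breakpoint, "limited", "non_limited")
  expect_equal(unname(cls$status), as.vector(truth))
})

test_that("critical point is the oblique/vertical intersection", {
  cp <- critical_point(c(-0.2, 3), 5)
  expect_equal(cp$dm, 5)
  expect_equal(cp$nc, 2)
  expect_equal(critical_point(c(0, 2.5), 7)$nc, 2.5)
  expect_error(critical_point(c(-1, 1), 2), "non-positive critical N")
  expect_error(critical_point(c(1, 1), -1), "positive")
})

test_that("allometric fit recovers power-law points exactly", {
  dm <- c(1, 2, 4, 8)
  fit <- fit_dilution_curve(dm, 2.24 * dm^(-0.35))
  expect_equal(unname(coef(fit)), c(2.24, 0.35), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  dm2 <- c(0.5, 1, 2, 4, 8)
  fit2 <- fit_dilution_curve(dm2, 2.78 * dm2^(-0.46))
  expect_equal(unname(coef(fit2)), c(2.78, 0.46), tolerance = 1e-10)
  expect_equal(c(fit2$dm_min, fit2$dm_max), c(0.5, 8))
})

test_that("allometric fit rejects degenerate inputs", {
  expect_error(fit_dilution_curve(c(1, 2), c(2, 1.5)), "at least 3")
  expect_error(fit_dilution_curve(c(1, 1, 1), c(2, 2, 2)), "distinct")
  expect_error(fit_dilution_curve(c(1, 2, 4), c(2, -1, 1)), "positive")
})

test_that("nonlinear refinement agrees on clean power-law data", {
  dm <- c(1, 2, 4, 8)
  fit <- fit_dilution_curve(dm, 2.24 * dm^(-0.35), refine = TRUE)
  expect_equal(unname(coef(fit)), c(2.24, 0.35), tolerance = 1e-6)
})

test_that("critical concentration evaluates the curve and warns off-range", {
  curve <- fit_dilution_curve(c(1, 2, 4, 8), 2.24 * c(1, 2, 4, 8)^(-0.35))
  expect_equal(critical_concentration(1, curve), 2.24, tolerance = 1e-10)
  expect_equal(critical_concentration(4, curve), 1.379, tolerance = 1e-3)
  expect_warning(critical_concentration(10, curve), "validity range")
  expect_error(critical_concentration(-1, curve), "positive")

  curve2 <- list(a = 2.78, b = 0.46)
  expect_equal(critical_concentration(1, curve2), 2.78)
})

test_that("critical concentration is strictly decreasing in biomass", {
  curve <- list(a = 2.24, b = 0.35)
  grid <- seq(0.3, 12, length.out = 60)
  expect_true(all(diff(critical_concentration(grid, curve)) < 0))
})

test_that("NNI is the measured-to-critical concentration ratio", {
  expect_equal(compute_nni(2.24, 2.24)$nni, 1)
  expect_equal(compute_nni(2.24, 2.24)$status, "optimal")
  expect_equal(compute_nni(1.5, 1.379)$nni, 1.088, tolerance = 1e-3)
  z <- compute_nni(0, 1.5)
  expect_equal(z$nni, 0)
  expect_equal(z$status, "deficient")
  expect_equal(compute_nni(2, 1.5)$status, "surplus")
  expect_error(compute_nni(1, 0), "positive")
})
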