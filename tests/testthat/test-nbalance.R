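test_that("yield target and grain N demand follow the balance formulas", {
  expect_equal(grain_yield(1.01, 10573.3), 10679.033)
  expect_equal(grain_yield(0, 9505.8), 0)
  expect_equal(grain_yield(1, 9505.8), 9505.8)

  expect_equal(grain_n_accumulation(10679.033, 1.97), 210.38,
               tolerance = 1e-4)
  expect_equal(grain_n_accumulation(0, 2.13), 0)
  expect_equal(grain_n_accumulation(9505.8, 2.13), 202.47,
               tolerance = 1e-4)
  expect_error(grain_yield(-1, 100), ">= 0")
  expect_error(grain_n_accumulation(100, -1), ">= 0")
})

test_that("required N implements the balance with clamping", {
  gna <- grain_n_accumulation(grain_yield(1.01, 10573.3), 1.97)
  expect_equal(as.numeric(required_n(gna, 128.90)), 191.26,
               tolerance = 5e-3)

  r0 <- required_n(100, 100, n_applied = 20)
  expect_equal(as.numeric(r0), 0)
  expect_false(attr(r0, "deficit"))

  expect_equal(as.numeric(required_n(202.47354, 118.56)), 196.98,
               tolerance = 5e-3)
  expect_error(required_n(100, 50, nue = 0), "nue")
  expect_error(required_n(-1, 50), ">= 0")
})

test_that("stage split reproduces the published 2:1 allocation", {
  p <- topdressing_plan(191.2605, 80, c(JT = 2, HD = 1))
  expect_equal(round(unname(p$topdressing), 2), c(74.17, 37.09))
  p2 <- topdressing_plan(196.9801, 64, c(JT = 2, HD = 1))
  expect_equal(round(unname(p2$topdressing), 2), c(88.65, 44.33))
  p3 <- topdressing_plan(196.9801, 80, c(JT = 2, HD = 1))
  expect_equal(round(unname(p3$topdressing), 2), c(77.99, 38.99))
})

test_that("plans conserve nitrogen exactly and validate inputs", {
  set.seed(61)
  for (i in 1:20) {
    tot <- runif(1, 50, 250); bas <- runif(1, 0, tot)
    ratios <- runif(sample(1:3, 1), 0.5, 3)
    p <- topdressing_plan(tot, bas, ratios)
    expect_lt(abs(p$basal + sum(p$topdressing) - p$total), 1e-9)
    expect_true(all(p$topdressing >= 0))
  }
  pz <- topdressing_plan(100, 100)
  expect_equal(unname(pz$topdressing), c(0, 0))
  expect_error(topdressing_plan(100, 120), "exceeds")
  expect_error(topdressing_plan(100, 50, c(-1, 2)), "positive")
})

test_that("end-to-end recommendation reproduces both published rows", {
  # saturated NNI, plateau_c policy: RY = c = 1.01
  plan_yj <- recommend_topdressing(1.2, plateau = list(slope = 1.088,
                                                       intercept = 0.08,
                                                       breakpoint = 1.01,
                                                       plateau = 1.01),
                                   y_max = 10573.3, apgn = 1.97,
                                   ns = 128.90, basal = 80,
                                   saturated_ry = "plateau_c")
  expect_equal(round(plan_yj$total, 2), 191.26)
  expect_equal(round(unname(plan_yj$topdressing), 2), c(74.17, 37.09))

  # second cultivar, unity policy: GY = Ymax
  jy <- list(slope = 2.266, intercept = 0.86, breakpoint = 0.82,
             plateau = 0.99)
  plan_n3 <- recommend_topdressing(1.0, jy, y_max = 9505.8, apgn = 2.13,
                                   ns = 118.56, basal = 64,
                                   split_ratios = c(TR = 2, JT = 1),
                                   saturated_ry = "unity")
  expect_equal(round(plan_n3$total, 2), 196.98)
  expect_equal(round(unname(plan_n3$topdressing), 2), c(88.65, 44.33))

  plan_n4 <- recommend_topdressing(1.0, jy, y_max = 9505.8, apgn = 2.13,
                                   ns = 118.56, basal = 80,
                                   split_ratios = c(TR = 2, JT = 1),
                                   saturated_ry = "unity")
  expect_equal(round(unname(plan_n4$topdressing), 2), c(77.99, 38.99))
})

test_that("replicate NNIs produce a mean plan with a spread column", {
  yjm <- list(slope = 1.088, intercept = 0.08, breakpoint = 1.01,
              plateau = 1.01)
  plan <- recommend_topdressing(c(0.92, 0.95, 0.98), yjm,
                                y_max = 10573.3, apgn = 1.97,
                                ns = 128.90, basal = 48)
  expect_gt(plan$rmse, 0)
  expect_lt(abs(plan$basal + sum(plan$topdressing) - plan$total), 1e-9)
  single <- recommend_topdressing(1.2, yjm, y_max = 10573.3, apgn = 1.97,
                                  ns = 128.90, basal = 80)
  expect_equal(single$rmse, 0)
})
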