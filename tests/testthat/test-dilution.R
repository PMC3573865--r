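test_that("dilution factors multiply and are order-invariant", {
  three <- dilution_step(rep(10, 3), rep(90, 3))
  expect_equal(total_factor(three), 1000)
  expect_equal(total_factor(dilution_step(10, 0)), 1)
  mixed <- dilution_step(rep(10, 4), c(90, 90, 90, 10))
  expect_equal(total_factor(mixed), 2000)
  expect_equal(total_factor(mixed[c(4, 2, 1, 3), ]), 2000)
  expect_error(total_factor(dilution_step(numeric(0), numeric(0))), "empty")
})

test_that("the error model interpolates CVs and refuses extrapolation", {
  m <- pipetting_error_model()
  expect_equal(cv_at_volume(m, c(1, 5, 10, 100)),
               c(0.08, 0.03, 0.01, 0.005))
  expect_equal(cv_at_volume(m, 7.5), 0.02)  # halfway between 3% and 1%
  expect_error(cv_at_volume(m, 0.5), "outside")
  expect_error(cv_at_volume(m, 200), "outside")
  expect_error(pipetting_error_model(c(1, 10), c(0.01, 0.05)),
               "non-increasing")
  expect_error(pipetting_error_model(c(10, 1), c(0.05, 0.01)),
               "increasing")
})

test_that("propagated CV combines independent steps in quadrature", {
  m <- pipetting_error_model()
  expect_equal(propagate_cv(dilution_step(10, 90), m), 0.01)
  expect_equal(propagate_cv(dilution_step(rep(5, 3), rep(45, 3)), m),
               sqrt(3) * 0.03)
  # the quantitative version of "3 x 1:10 beats 1 x 1:1000"
  expect_equal(propagate_cv(dilution_step(1, 999), m), 0.08)
  expect_equal(propagate_cv(dilution_step(rep(10, 3), rep(90, 3)), m),
               sqrt(3) * 0.01)
})

test_that("the planner decomposes ratios into minimal admissible steps", {
  p <- plan_serial_dilution(10000, 10)
  expect_equal(nrow(p$steps), 3L)
  expect_equal(p$steps$factor, rep(10, 3))
  expect_equal(p$final_copies, 10)

  p2 <- plan_serial_dilution(10000, 5)
  expect_equal(nrow(p2$steps), 4L)
  expect_equal(p2$total_factor, 2000)
  expect_equal(p2$steps$factor, c(10, 10, 10, 2))  # smallest factor last
  expect_equal(p2$final_copies, 5)

  same <- plan_serial_dilution(100, 100)
  expect_equal(nrow(same$steps), 0L)
  expect_equal(same$total_factor, 1)
  expect_equal(same$total_cv, 0)

  expect_error(plan_serial_dilution(10, 100), "concentrate")
  expect_error(plan_serial_dilution(100, 0), "> 0")
  expect_error(plan_serial_dilution(100, 1, step_volume = 0.5),
               "minimum pipettable")
})

test_that("plans conserve copy number: final x factor == source", {
  set.seed(3)
  for (i in 1:25) {
    src <- 10^runif(1, 3, 8)
    tgt <- src / 10^runif(1, 0, 4)
    p <- plan_serial_dilution(src, tgt)
    expect_equal(p$final_copies * p$total_factor, src, tolerance = 1e-9)
    expect_equal(p$final_copies, tgt, tolerance = 1e-9)
    expect_true(all(p$steps$factor <= 10 + 1e-9))
    expect_gte(p$total_cv, max(c(0, p$steps$step_cv)))
  }
})

test_that("planner step count matches exhaustive integer enumeration", {
  # 10-smooth ratios that admit an integer decomposition at the log bound
  for (ratio in c(2, 8, 10, 36, 100, 240, 512, 1000, 2000, 6480, 10000)) {
    p <- plan_serial_dilution(ratio * 100, 100)
    expect_equal(nrow(p$steps), min_integer_steps(ratio),
                 info = paste("ratio", ratio))
  }
  # the planner's count is a lower bound even when integers cannot reach it
  expect_equal(nrow(plan_serial_dilution(768 * 10, 10)$steps), 3L)
  expect_equal(min_integer_steps(768), 4L)
})

test_that("splitting a large step into small ones reduces propagated error", {
  m <- pipetting_error_model()
  set.seed(9)
  for (i in 1:20) {
    f <- runif(1, 2, 10)
    total_vol <- 100
    a_big <- total_vol / f^2
    a_small <- total_vol / f
    if (a_big < 1) next
    combined <- dilution_step(a_big, total_vol - a_big)
    split <- dilution_step(rep(a_small, 2), rep(total_vol - a_small, 2))
    cv_c <- propagate_cv(combined, m)
    cv_s <- propagate_cv(split, m)
    if (sqrt(2) * cv_at_volume(m, a_small) <= cv_at_volume(m, a_big)) {
      expect_lte(cv_s, cv_c)
    }
    expect_equal(total_factor(split), total_factor(combined),
                 tolerance = 1e-9)
  }
})

test_that("compare_plans orders by propagated CV and checks comparability", {
  three <- plan_serial_dilution(1e6, 1e3)
  one <- plan_serial_dilution(1e6, 1e3, max_step_factor = 1000,
                              step_volume = 1)
  cmp <- compare_plans(three, one)
  expect_equal(cmp$winner, "a")
  expect_lt(cmp$cv_a, cmp$cv_b)
  expect_equal(compare_plans(three, three)$winner, "equivalent")
  expect_error(compare_plans(three, plan_serial_dilution(1e6, 1e2)),
               "not comparable")
})
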