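test_that("milestone sets are well-formed for each stage", {
  for (st in 1:3) {
    ms <- milestone_set(st)
    expect_gt(nrow(ms), 0L)
    expect_true(all(ms$comparator %in% c("le", "eq")))
    expect_true(all(ms$stage == st))
  }
})

test_that("packaged defaults satisfy the stage-1 kinetic milestones", {
  cal_obs <- dsdfibril:::stage1_observables(rate_params())
  expect_lte(cal_obs[["cy5_peak_min"]], 10)
  expect_lt(abs(cal_obs[["completion_h"]] - 2) / 2, 0.25)
  expect_lte(cal_obs[["cy5_end_frac"]], 0.05)
})

test_that("stage-1 calibration is deterministic and feasible from defaults", {
  c1 <- calibrate(stage = 1, maxit = 8L)
  c2 <- calibrate(stage = 1, maxit = 8L)
  expect_identical(c1$params, c2$params)
  expect_true(c1$feasible)
  expect_s3_class(c1$params, "dsd_rate_params")
  expect_true(all(c("observable", "achieved", "met") %in% names(c1$report)))
})

test_that("infeasible calibration reports the unmet milestones", {
  # an absurdly slow saturated rate cannot reach the 10-min Cy5 peak
  slow <- rate_params(k_max = 1e-7, h = 1e-3)
  expect_warning(
    cal <- calibrate(stage = 1, p = slow, maxit = 1L),
    "unmet"
  )
  expect_false(cal$feasible)
  expect_true(any(!cal$report$met))
})

test_that("stage-2 leaves stage-1 parameters untouched and keeps rho < 1", {
  p <- rate_params()
  cal <- calibrate(stage = 2, p = p, maxit = 10L)
  expect_identical(cal$params$k_max, p$k_max)
  expect_identical(cal$params$h, p$h)
  expect_lt(cal$params$rho, 1)
})
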