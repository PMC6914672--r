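test_that("decay and recovery rates follow the threshold geometry", {
  # 16 h from full satiation to threshold 0.2
  expect_equal(decay_rate(0.2, 16), -0.05)
  expect_equal(decay_rate(0.2, 3.5), -0.8 / 3.5)
  # rate vanishes as the threshold approaches full satiation
  expect_lt(abs(decay_rate(1 - 1e-12, 16)), 1e-12)
  expect_error(decay_rate(0.2, 0), "> 0")

  expect_equal(recovery_rate(0.2, 0.5), 1.6)
  expect_equal(recovery_rate(0.2, 0.25), 3.2)
  expect_error(recovery_rate(0.2, -1), "> 0")

  # sign symmetry: recovery is the mirrored decay
  lam <- runif(20, 0.05, 0.95)
  d <- runif(20, 0.1, 20)
  expect_equal(recovery_rate(lam, d), -decay_rate(lam, d))
})

test_that("activity duration reaches full satiation and honors the minimum", {
  # starting exactly at threshold takes exactly the minimum recovery time
  expect_equal(activity_duration(0.2, recovery_rate(0.2, 0.5)), 0.5)
  expect_equal(activity_duration(0, 1.6), 0.625)
  expect_equal(activity_duration(1, 1.6), 0)
  expect_error(activity_duration(0.5, 0), "> 0")

  # identity holds for arbitrary thresholds and minimum times
  lam <- runif(50, 0.01, 0.99)
  d <- runif(50, 0.01, 24)
  expect_equal(activity_duration(lam, recovery_rate(lam, d)), d)

  # starting below threshold always takes longer than the minimum
  expect_gt(activity_duration(0.1, recovery_rate(0.2, 10)), 10)
})

test_that("recovered trajectory lands exactly at full satiation", {
  lam <- 0.2
  for (n0 in c(0.2, 0.13, 0.05, 0)) {
    plan <- recovery_plan(n0, lam, 10)
    n_final <- n0 + plan$m_recover * plan$dt_activity
    expect_equal(n_final, 1)
    # and within one tick when durations are rounded to whole minutes
    n_tick <- n0 + plan$m_recover * plan$dt_activity_min / 60
    expect_lt(abs(n_tick - 1), plan$m_recover / 60 + 1e-12)
  }
})

test_that("step satiation switches from 1 to eta at the trigger", {
  expect_equal(step_satiation(100, 200, 0.1), 1)
  expect_equal(step_satiation(200, 200, 0.1), 0.1)
  expect_equal(step_satiation(300, 200, 0.1), 0.1)
  # once satisfied, satiation is 1 from the satisfaction time onward
  expect_equal(step_satiation(250, Inf, 0), 1)
  expect_error(step_satiation(0, 0, 0.5, lambda_thr = 0.2), "eta")
})

test_that("urgency weight is zero above threshold, finite and decreasing below", {
  expect_equal(need_weight(0.5, 0.2), 0)
  expect_equal(need_weight(0.2, 0.2, 1e-9), 1 / (0.2 + 1e-9))
  expect_equal(need_weight(0, 0.2, 1e-9), 1e9)
  expect_error(need_weight(0.1, 0.2, epsilon = 0), "> 0")

  n <- sort(runif(50, 0, 0.2))
  w <- need_weight(n, 0.2)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 1 / (0.2 + 1e-9) - 1e-6))
  expect_true(all(is.finite(w)))
})

test_that("score sign tracks the promised satiation change", {
  expect_equal(need_score(0.3, 1, 0.2), 0)          # above threshold
  expect_equal(need_score(0.2, 1, 0.2, 1e-9),
               1 / (0.2 + 1e-9) - 1 / (1 + 1e-9))   # about 4
  expect_lt(need_score(0.2, 0.1, 0.2), 0)           # harmful activity
  # a no-change activity scores zero at any unsatisfied level
  n <- runif(20, 0, 0.2)
  expect_equal(need_score(n, n, 0.2), rep(0, 20))
})

test_that("linear needs clamp to [0, 1] under any advance", {
  nd <- need("Rest", "linear", n = 1, m_decay = -0.05)
  nd <- advance_linear(nd, 960)          # 16 h at -0.05/h
  expect_equal(nd$n, 0.2)
  nd2 <- advance_linear(nd, 1e6)
  expect_equal(nd2$n, 0)                 # clamped, never negative
  nd3 <- need("Hunger", "linear", n = 0.5, m_decay = 0)
  expect_equal(advance_linear(nd3, 500)$n, 0.5)
  expect_error(advance_linear(need("Income", "step"), 10), "linear")
})
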