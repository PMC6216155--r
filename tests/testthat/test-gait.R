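test_that("uniform cycles give the textbook contact/swing/cadence values", {
  ct <- cycle_times(seq(0, by = 0.75, length.out = 12), rep(0.30, 12))
  gs <- summarize_cycles(ct)
  expect_equal(gs$contact_mean, 300)
  expect_equal(gs$swing_mean, 450)
  expect_equal(gs$cadence_mean, 160)
  expect_equal(gs$contact_sd, 0)
})

test_that("typical running cycle times give a cadence near 162 steps/min", {
  # contact 288 ms + swing 452 ms -> 740 ms cycles
  ct <- cycle_times(seq(0, by = 0.740, length.out = 31), rep(0.288, 31))
  gs <- summarize_cycles(ct)
  expect_equal(gs$contact_mean, 288)
  expect_equal(gs$swing_mean, 452)
  expect_equal(gs$cadence_mean, 2 * 60 / 0.740, tolerance = 1e-12)
  expect_lt(abs(gs$cadence_mean - 163), 10)  # inside the cohort band
})

test_that("summaries match a direct arithmetic oracle on randomized tables", {
  set.seed(81)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    cyc <- runif(n, 0.6, 0.9)
    td <- c(0, cumsum(cyc))
    st <- runif(n + 1, 0.2, 0.35)
    st <- pmin(st, c(cyc, Inf) - 0.01)
    ct <- cycle_times(td, st)
    gs <- summarize_cycles(ct)
    want <- oracle_gait(td, st)
    expect_equal(gs$contact_mean, want$contact_mean)
    expect_equal(gs$swing_mean, want$swing_mean)
    expect_equal(gs$cadence_mean, want$cadence_mean)
  }
  expect_error(summarize_cycles(cycle_times(0.1, 0.3)), "two touchdowns")
})

test_that("cycle summaries of generated trials recover the cycle model", {
  gt <- make_ground_truth(seed = 82)
  sim <- synthesize_trial(gt, n_cycles = 150, seed = 82, duration = 120)
  gs <- summarize_cycles(sim$ct)
  expect_lt(abs(gs$contact_mean - 288), 2 * 42 / sqrt(150) * 1.5)
  expect_lt(abs(gs$swing_mean - 452), 2 * 45 / sqrt(149) * 1.5)
})

test_that("the strike index is the on-axis heel-to-pressure distance over foot length", {
  heel <- c(0, 0); toe <- c(0.25, 0)
  expect_equal(strike_index(heel, toe, heel), 0)
  expect_equal(strike_index(heel, toe, toe), 1)
  expect_equal(strike_index(heel, toe, c(0.05, 0)), 0.2)
  expect_equal(strike_index(heel, toe, c(0.05, 0.03)), 0.2)  # off-axis projected
  expect_error(strike_index(heel, toe, c(1, 2, 3)), "dimension")
  expect_error(strike_index(heel, heel, c(0.1, 0)), "zero")
})

test_that("the synthetic pressure geometry round-trips the strike index exactly", {
  for (si in seq(0, 1, by = 0.1)) {
    g <- make_cop_trace(0.27, si, seed = round(100 * si) + 1)
    expect_equal(strike_index(g$heel, g$toe, g$cop), si, tolerance = 1e-9)
  }
})

test_that("foot strike patterns split at a strike index of one third", {
  expect_equal(foot_strike_class(0.152), "rearfoot")
  expect_equal(foot_strike_class(0.333), "midfoot-forefoot")  # strict less-than
  expect_equal(foot_strike_class(0.699), "midfoot-forefoot")
  expect_equal(foot_strike_class(0), "rearfoot")
  expect_error(foot_strike_class(1.2), "\\[0, 1\\]")
  expect_error(foot_strike_class(-0.1), "\\[0, 1\\]")
})
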