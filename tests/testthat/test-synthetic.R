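test_that("rank-4 ground truth places one bump per functional quadrant", {
  for (seed in 1:10) {
    gt <- make_ground_truth(seed = seed)
    expect_true(all(gt$W_true >= 0))
    expect_true(all(gt$H_true >= 0))
    expect_equal(apply(gt$H_true, 1, max), rep(1, 4))  # unit peaks
    peaks <- apply(gt$H_true, 1, which.max)
    quadrant <- findInterval(peaks, c(1, 51, 101, 151))
    expect_equal(quadrant, 1:4)
  }
})

test_that("plantar flexors dominate the propulsion module", {
  for (seed in 1:10) {
    gt <- make_ground_truth(seed = seed)
    w2 <- gt$W_true[, 2]
    pf <- c("PL", "GM", "GL", "SO")
    expect_gt(min(w2[pf]), max(w2[setdiff(emg_muscles(), pf)]))
  }
})

test_that("degenerate ranks and rank bounds behave", {
  gt1 <- make_ground_truth(r = 1, seed = 3)
  expect_equal(nrow(gt1$H_true), 1L)
  expect_equal(sum(diff(sign(diff(gt1$H_true[1, ]))) < 0), 1L)  # single bump
  expect_true(all(gt1$W_true[, 1] > 0))
  expect_error(make_ground_truth(m = 5, r = 6), "r <= m")
})

test_that("drawn cycle durations match the cycle model", {
  gt <- make_ground_truth(seed = 11, noise_sd = 0)
  sim <- synthesize_trial(gt, n_cycles = 200, seed = 11, duration = 160)
  contact <- sim$ct$stance
  swing <- diff(sim$touchdowns) - contact
  # means within ~3 standard errors of the model values
  expect_lt(abs(mean(contact) - 0.288), 3 * 0.042 / sqrt(200))
  expect_lt(abs(mean(swing) - 0.452), 3 * 0.045 / sqrt(200))
  expect_true(all(contact > 0) && all(swing > 0))
  expect_equal(nrow(sim$ct), 200L)
})

test_that("noise-free constant-carrier trial has rectified signal equal to the envelope", {
  sim <- quick_sim(seed = 2, n_cycles = 6, noise_sd = 0, carrier = "constant")
  expect_equal(t(abs(sim$trial$emg)), sim$envelope, ignore_attr = TRUE)
})

test_that("synthesis is reproducible from the seed", {
  gt <- make_ground_truth(seed = 5)
  a <- synthesize_trial(gt, n_cycles = 5, seed = 99, duration = 6)
  b <- synthesize_trial(gt, n_cycles = 5, seed = 99, duration = 6)
  expect_identical(a$trial$emg, b$trial$emg)
  expect_identical(a$ct, b$ct)
  d <- synthesize_trial(gt, n_cycles = 5, seed = 100, duration = 6)
  expect_false(identical(a$trial$emg, d$trial$emg))
})

test_that("synthetic metadata has plausible, in-range values", {
  meta <- make_metadata(135, seed = 8)
  expect_equal(nrow(meta), 135L)
  expect_true(all(meta$SI >= 0 & meta$SI <= 1, na.rm = TRUE))
  expect_true(all(meta$Speed > 0))
  expect_true(all(meta$Sex %in% c("M", "F")))
  expect_equal(nrow(make_metadata(1, seed = 1)), 1L)
  expect_identical(make_metadata(20, seed = 3), make_metadata(20, seed = 3))
})

test_that("synthetic foot geometry encodes the requested strike index", {
  g0 <- make_cop_trace(0.25, 0, seed = 1)
  expect_equal(strike_index(g0$heel, g0$toe, g0$cop), 0)
  g1 <- make_cop_trace(0.25, 1, seed = 2)
  expect_equal(strike_index(g1$heel, g1$toe, g1$cop), 1)
  g <- make_cop_trace(0.25, 0.2, seed = 3)
  axis <- (g$toe - g$heel) / 0.25
  expect_equal(sum((g$cop - g$heel) * axis), 0.05, tolerance = 1e-12)
})

test_that("a simulated cohort writes a complete deposited-style file tree", {
  dir <- withr::local_tempdir()
  gts <- simulate_cohort(2, dir, n_cycles = 3, seed = 7,
                         trials_per_participant = 2)
  expect_length(gts, 2L)
  files <- list.files(dir)
  expect_setequal(files, c(
    sprintf("RAW_EMG_P%04d_%02d.dat", rep(1:2, each = 2), rep(1:2, 2)),
    sprintf("CYCLE_TIMES_P%04d_%02d.dat", rep(1:2, each = 2), rep(1:2, 2)),
    "participants_data.dat"))
  ct <- read_cycle_times(file.path(dir, "CYCLE_TIMES_P0002_02.dat"))
  expect_equal(nrow(ct), 3L)
})
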