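test_that("the envelope cascade matches an independently coded reference filter", {
  t <- (0:1999) / 1000
  x <- sin(2 * pi * 10 * t)
  got <- make_envelope(x)
  want <- oracle_envelope(x)
  expect_lt(sqrt(mean((got - want)^2)), 1e-6)
})

test_that("a constant input leaves only a tiny positive floor away from the edges", {
  env <- make_envelope(rep(5, 2000))
  expect_true(all(env > 0))
  # DC is removed by the high-pass; only the filter's start-up/run-out
  # transients retain visible energy at the record edges
  expect_lt(max(env[300:1700]), 1e-8)
})

test_that("envelopes are strictly positive with no zeros on arbitrary signals", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(1500) * rbinom(1500, 1, 0.7)  # includes runs of exact zeros
    env <- make_envelope(x)
    expect_true(all(env > 0))
    expect_length(env, 1500L)
  }
})

test_that("degenerate inputs to the envelope are rejected", {
  expect_error(make_envelope(rnorm(50)), "short")
  expect_error(make_envelope(c(rnorm(1000), NaN)), "NA")
})

test_that("amplitude normalization uses the per-muscle maximum across both trials", {
  set.seed(3)
  a <- matrix(runif(13 * 50, 0.1, 2), 13, dimnames = list(emg_muscles(), NULL))
  b <- matrix(runif(13 * 50, 0.1, 2), 13, dimnames = list(emg_muscles(), NULL))
  a["TA", ] <- a["TA", ] / max(a["TA", ]) * 2  # trial A max 2.0
  b["TA", ] <- b["TA", ] / max(b["TA", ]) * 4  # trial B max 4.0
  norm <- normalize_amplitude(list(a, b))
  expect_equal(norm[[1]]["TA", ], a["TA", ] / 4)
  expect_equal(norm[[2]]["TA", ], b["TA", ] / 4)
  # per-muscle global max is exactly 1, and renormalizing changes nothing
  gmax <- apply(cbind(norm[[1]], norm[[2]]), 1, max)
  expect_equal(gmax, setNames(rep(1, 13), emg_muscles()))
  expect_equal(normalize_amplitude(norm), norm)
})

test_that("per-muscle maxima equal one across randomized synthetic trial pairs", {
  for (seed in 1:5) {
    gt <- make_ground_truth(seed = seed, noise_sd = 0.1)
    sims <- lapply(1:2, function(j) {
      synthesize_trial(gt, n_cycles = 3, seed = seed + 10 * j, duration = 4)
    })
    envs <- normalize_amplitude(lapply(sims, function(s) {
      t(apply(s$trial$emg, 2, make_envelope))
    }))
    expect_equal(apply(do.call(cbind, envs), 1, max),
                 setNames(rep(1, 13), emg_muscles()))
  }
})

test_that("a constant-floor channel triggers a warning, not an error", {
  a <- matrix(1, 13, 20, dimnames = list(emg_muscles(), NULL))
  a[-1, ] <- matrix(runif(12 * 20, 0.1, 2), 12)
  expect_warning(normalize_amplitude(list(a)), "ME")
})

test_that("time normalization produces 200 points per cycle, 6000 for 30 cycles", {
  sim <- quick_sim(seed = 13, n_cycles = 30)
  env <- t(apply(sim$trial$emg, 2, make_envelope))
  V <- time_normalize(env, sim$ct, n_cycles = 30)
  expect_equal(ncol(V), 6000L)
  expect_equal(attr(V, "cycles"), 30L)
  expect_equal(attr(V, "points_per_cycle"), 200L)
})

test_that("resampling a constant stance returns the constant", {
  # one cycle: stance of exactly 100 samples (0.1 s at 1 kHz), constant value
  env <- matrix(0.3, 13, 1000, dimnames = list(emg_muscles(), NULL))
  ct <- cycle_times(c(0.1, 0.7), c(0.1, 0.1))
  V <- time_normalize(env, ct, n_cycles = 1)
  expect_equal(unname(V[1, 1:100]), rep(0.3, 100))
})

test_that("linear signals are reproduced exactly by the interpolating grid", {
  # channel = a + b * t; linear interpolation must return the closed form
  a <- 0.2; b <- 1.5
  tgrid <- (0:999) / 1000
  env <- matrix(rep(a + b * tgrid, each = 13), 13,
                dimnames = list(emg_muscles(), NULL))
  ct <- cycle_times(c(0.05, 0.71), c(0.26, 0.26))
  V <- time_normalize(env, ct, n_cycles = 1)
  se <- 0.05 + 0.26
  q <- c(seq(0.05, se, length.out = 100), se + (0:99) / 100 * (0.71 - se))
  expect_equal(unname(V[4, ]), a + b * q, tolerance = 1e-9)
})

test_that("asking for more cycles than the table holds is an error", {
  sim <- quick_sim(seed = 14, n_cycles = 5)
  env <- t(apply(sim$trial$emg, 2, make_envelope))
  expect_error(time_normalize(env, sim$ct, n_cycles = 10), "5")
})

test_that("the conditioning chain recovers the generating envelope on noise-free data", {
  sim <- quick_sim(seed = 7, n_cycles = 30, noise_sd = 0)
  env <- preprocess_trials(list(sim$trial), list(sim$ct), n_cycles = 30)[[1]]
  gt <- sim$gt
  Vbar <- vapply(1:13, function(i) mean_cycle(env[i, ]), numeric(200))
  true <- t(gt$W_true %*% gt$H_true)
  Vbar <- sweep(Vbar, 2, apply(Vbar, 2, max), "/")
  true <- sweep(true, 2, apply(true, 2, max), "/")
  interior <- 9:192  # away from the touchdown boundaries
  err <- Vbar[interior, ] - true[interior, ]
  rel_rms <- sqrt(mean(err^2)) / sqrt(mean(true[interior, ]^2))
  expect_lt(rel_rms, 0.05)
})
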