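test_that("cycle averaging is the pointwise mean across cycles", {
  one <- sin(seq(0, pi, length.out = 200))
  expect_equal(mean_cycle(rep(one, 2)), one)
  expect_equal(mean_cycle(c(0, 2, 2, 0), points_per_cycle = 2), c(1, 1))
  expect_error(mean_cycle(rep(1, 300)), "multiple")
})

test_that("the cycle mean of noisy repeated bumps stays within 3 standard errors", {
  set.seed(61)
  bump <- exp(-((1:200) - 80)^2 / 200)
  noise_sd <- 0.05
  x <- rep(bump, 30) + rnorm(6000, 0, noise_sd)
  m <- mean_cycle(x)
  se <- noise_sd / sqrt(30)
  expect_gt(mean(abs(m - bump) < 3 * se), 0.98)
  expect_true(all(abs(m - bump) < 6 * se))
})

test_that("single and double bumps classify as fundamental and combined", {
  pts <- 1:200
  one <- exp(-(pts - 100)^2 / (2 * 15^2))
  cl1 <- classify_primitive(one)
  expect_equal(cl1$kind, "fundamental")
  expect_equal(cl1$peak_count, 1L)

  two <- exp(-(pts - 50)^2 / (2 * 12^2)) + exp(-(pts - 150)^2 / (2 * 12^2))
  cl2 <- classify_primitive(two)
  expect_equal(cl2$kind, "combined")
  expect_equal(cl2$peak_count, 2L)

  expect_error(classify_primitive(rep(0.5, 200)), "constant")
})

test_that("ripple below the prominence floor does not create extra peaks", {
  pts <- 1:200
  bump <- exp(-(pts - 60)^2 / (2 * 15^2))
  ripple <- 0.08 * (1 + sin(2 * pi * pts / 40)) / 2  # max 0.08 < 0.1 floor
  y <- pmax(bump, ripple)
  cl <- classify_primitive(y)
  expect_equal(cl$kind, "fundamental")
  # the same ripple raised above the floor does register
  y2 <- pmax(bump, ripple * 3)
  expect_equal(classify_primitive(y2)$kind, "combined")
})

test_that("phase labels follow the quadrant of the main peak", {
  pts <- 1:200
  mk <- function(center) {
    cl <- classify_primitive(exp(-(pts - center)^2 / (2 * 10^2)))
    cl$main_peak <- cl$peaks[1]
    cl
  }
  expect_equal(label_synergies(list(mk(10))), "weight-acceptance")
  expect_equal(label_synergies(list(mk(70))), "propulsion")
  expect_equal(label_synergies(list(mk(120))), "early-swing")
  expect_equal(label_synergies(list(mk(180))), "late-swing")
  combined <- classify_primitive(exp(-(pts - 40)^2 / 100) +
                                   exp(-(pts - 160)^2 / 100))
  expect_equal(label_synergies(list(combined)), "none")
})

test_that("generated primitive templates always classify as fundamental", {
  for (seed in 1:20) {
    gt <- make_ground_truth(seed = seed)
    for (i in 1:4) {
      expect_equal(classify_primitive(gt$H_true[i, ])$kind, "fundamental")
    }
    blend <- gt$H_true[1, ] + gt$H_true[3, ]  # disjoint quadrants
    expect_equal(classify_primitive(blend)$kind, "combined")
  }
})

test_that("classification of a synergy set is permutation-equivariant", {
  gt <- make_ground_truth(seed = 71)
  H <- gt$H_true[, rep(1:200, 3)]
  W <- gt$W_true
  syn <- synergy_set(W, H, r_squared = 1, iterations = 1L)
  cls <- classify_synergies(syn)
  perm <- c(3, 1, 4, 2)
  syn_p <- synergy_set(W[, perm], H[perm, ], r_squared = 1, iterations = 1L)
  cls_p <- classify_synergies(syn_p)
  expect_equal(cls_p$label, cls$label[perm])
  expect_equal(cls_p$kind, cls$kind[perm])
  expect_true(all(cls$kind == "fundamental"))
  expect_equal(cls$label,
               c("weight-acceptance", "propulsion", "early-swing", "late-swing"))
})
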