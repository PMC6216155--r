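#' Ground truth for a synthetic running trial
#'
#' Builds the generating quantities of a synthetic trial: non-negative motor
#' modules `W_true` (muscles x rank) and 200-point per-cycle motor-primitive
#' templates `H_true` (rank x 200, single Gaussian bumps with unit peak),
#' plus the envelope noise level and the gait-cycle duration model. For the
#' default rank 4 the bumps are centered in the four functional quadrants of
#' the cycle — weight acceptance (early stance), propulsion (late stance),
#' early swing, late swing — and the modules emphasize the corresponding
#' muscle groups: knee extensors and glutei; plantar flexors; dorsiflexors;
#' knee flexors and dorsiflexors. Within-group weights are drawn uniformly
#' on (0.6, 1) and off-group weights on (0, 0.15), so magnitudes are random
#' but group structure is fixed. For other ranks, bump centers are evenly
#' spaced over the cycle and each synergy emphasizes a random muscle subset.
#'
#' @param m Number of muscles (default 13, the canonical set).
#' @param r Number of synergies, `1 <= r <= m` (default 4).
#' @param seed Integer seed.
#' @param noise_sd Relative standard deviation of the multiplicative
#'   envelope noise (default 0.1; truncated at zero during synthesis).
#' @param cycle_model Mean/sd of the contact and swing durations in seconds
#'   (defaults: contact 0.288 +/- 0.042 s, swing 0.452 +/- 0.045 s).
#' @param bump_sd Width (s.d.) of the Gaussian primitive bumps in cycle
#'   points (default 15, i.e. 7.5% of the 200-point cycle).
#' @return An object of class `synergy_ground_truth` with elements `W_true`,
#'   `H_true`, `noise_sd`, `cycle_model`, `seed`, `m`, `r`.
#' @export
make_ground_truth <- function(m = 13L, r = 4L, seed = 1L, noise_sd = 0.1,
                              cycle_model = list(contact_mean = 0.288,
                                                 contact_sd = 0.042,
                                                 swing_mean = 0.452,
                                                 swing_sd = 0.045),
                              bump_sd = 15) {
  if (r < 1L || r > m) {
    stop(sprintf("'r' must satisfy 1 <= r <= m (got r = %d, m = %d)", r, m),
         call. = FALSE)
  }
  set.seed(seed)
  pts <- seq_len(200L)
  if (r == 4L) {
    centers <- c(25, 75, 125, 175) + runif(4, -10, 10)
  } else {
    centers <- (seq_len(r) - 0.5) * 200 / r + runif(r, -5, 5)
  }
  H_true <- t(vapply(centers, function(cc) {
    b <- exp(-(pts - cc)^2 / (2 * bump_sd^2))
    b / max(b)  # unit peak
  }, numeric(200L)))

  muscles <- if (m == 13L) emg_muscles() else sprintf("M%02d", seq_len(m))
  W_true <- matrix(runif(m * r, 0, 0.15), m, r,
                   dimnames = list(muscles, NULL))
  if (m == 13L && r == 4L) {
    groups <- list(c("ME", "MA", "RF", "VM", "VL"),  # weight acceptance
                   c("PL", "GM", "GL", "SO"),        # propulsion
                   c("TA", "FL"),                    # early swing
                   c("ST", "BF", "TA"))              # late swing
  } else {
    groups <- lapply(seq_len(r), function(i) {
      sample(muscles, size = max(2L, m %/% r))
    })
  }
  for (i in seq_len(r)) {
    W_true[groups[[i]], i] <- runif(length(groups[[i]]), 0.6, 1)
  }
  structure(list(W_true = W_true, H_true = H_true, noise_sd = noise_sd,
                 cycle_model = cycle_model, seed = seed,
                 m = as.integer(m), r = as.integer(r)),
            class = "synergy_ground_truth")
}

#' @export
print.synergy_ground_truth <- function(x, ...) {
  cat(sprintf("<synergy_ground_truth> %d muscles, rank %d, noise_sd %.2f, seed %d\n",
              x$m, x$r, x$noise_sd, x$seed))
  invisible(x)
}

rtrunc_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

warp_template <- function(H_true, u, phase) {
  # phase 1 = stance (template cols 1..100), 2 = swing (cols 101..200).
  # Grids mirror time_normalize(): stance spans [0, 1] inclusive;
  # swing spans [0, 1) half-open at the next touchdown.
  cols <- if (phase == 1L) 1:100 else 101:200
  xg <- if (phase == 1L) seq(0, 1, length.out = 100L) else (0:99) / 100
  t(vapply(seq_len(nrow(H_true)), function(i) {
    approx(xg, H_true[i, cols], xout = u, rule = 2)$y
  }, numeric(length(u))))
}

#' Synthesize a raw-EMG-like trial from a ground truth
#'
#' Generates one trial: gait-cycle durations are drawn from the ground
#' truth's cycle model (truncated at zero, redrawing non-positive values);
#' the per-muscle activation envelope is `W_true` times the per-cycle
#' time-warped primitive templates, perturbed by multiplicative truncated
#' Gaussian noise `max(0, 1 + e)`, `e ~ N(0, noise_sd)`; and each raw EMG
#' channel is the envelope amplitude-modulating a zero-mean band-limited
#' (20-450 Hz) Gaussian carrier scaled to unit mean absolute value, whose
#' rectified, low-pass-filtered version approximates the envelope. With
#' `carrier = "constant"` the carrier is 1, so the rectified raw signal
#' equals the envelope exactly (a degenerate case used for validation).
#' Everything is reproducible from the seed.
#'
#' @param gt A [make_ground_truth()] object.
#' @param n_cycles Number of gait cycles (default 30; the cycle-times table
#'   gets one row per cycle).
#' @param fs Sampling frequency in Hz (default 1000).
#' @param duration Minimum trial duration in seconds (default 30, the
#'   canonical 30000-sample trial; extended if the cycles need more).
#' @param carrier `"bandlimited"` (default) or `"constant"`.
#' @param seed Integer seed (defaults to the ground truth's seed).
#' @param participant,trial Identity stamped on the generated trial.
#' @return A list: `trial` (an [emg_trial()]), `ct` (a [cycle_times()] table
#'   with `n_cycles` rows), `envelope` (the true noisy 13 x samples
#'   envelope), `touchdowns` (all `n_cycles + 1` touchdown instants,
#'   including the one closing the last cycle) and `gt`.
#' @export
synthesize_trial <- function(gt, n_cycles = 30L, fs = 1000, duration = 30,
                             carrier = c("bandlimited", "constant"),
                             seed = gt$seed, participant = "P0001",
                             trial = 1L) {
  stopifnot(inherits(gt, "synergy_ground_truth"), n_cycles >= 1L)
  carrier <- match.arg(carrier)
  set.seed(seed)
  cm <- gt$cycle_model
  contact <- rtrunc_pos(n_cycles, cm$contact_mean, cm$contact_sd)
  swing <- rtrunc_pos(n_cycles, cm$swing_mean, cm$swing_sd)
  td <- 0.25 + c(0, cumsum(contact + swing))  # n_cycles + 1 touchdowns
  total <- max(duration, td[n_cycles + 1L] + 0.25)
  n <- round(total * fs)
  tgrid <- (seq_len(n) - 1) / fs

  m <- gt$m
  E <- matrix(0, m, n, dimnames = list(rownames(gt$W_true), NULL))
  for (k in seq_len(n_cycles)) {
    se <- td[k] + contact[k]
    in_st <- which(tgrid >= td[k] & tgrid < se)
    in_sw <- which(tgrid >= se & tgrid < td[k + 1L])
    if (length(in_st)) {
      u <- (tgrid[in_st] - td[k]) / contact[k]
      E[, in_st] <- gt$W_true %*% warp_template(gt$H_true, u, 1L)
    }
    if (length(in_sw)) {
      u <- (tgrid[in_sw] - se) / (td[k + 1L] - se)
      E[, in_sw] <- gt$W_true %*% warp_template(gt$H_true, u, 2L)
    }
  }
  if (gt$noise_sd > 0) {
    E <- E * pmax(0, 1 + rnorm(length(E), 0, gt$noise_sd))
  }

  if (carrier == "constant") {
    raw <- E
  } else {
    bp <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
    raw <- t(vapply(seq_len(m), function(i) {
      ci <- signal::filtfilt(bp, rnorm(n))
      ci <- ci / mean(abs(ci))  # unit mean rectified amplitude
      E[i, ] * ci
    }, numeric(n)))
    rownames(raw) <- rownames(E)
  }

  list(trial = emg_trial(tgrid, t(raw), participant = participant,
                         trial = trial),
       ct = cycle_times(td[seq_len(n_cycles)], contact),
       envelope = E,
       touchdowns = td,
       gt = gt)
}

#' Synthetic participants metadata
#'
#' Generates a plausible participants table: height ~ 175 +/- 9 cm, mass ~
#' 69 +/- 11 kg, age ~ 30 +/- 5 y, running speed ~ 2.65 +/- 0.31 m/s
#' (truncated positive), sex drawn at the cohort's 78:57 male:female ratio,
#' speed type PR (preferred) or FX (fixed), and a strike index drawn from a
#' Beta distribution with mean 0.152 and s.d. 0.195 (a right-skewed,
#' mostly-rearfoot cohort). Participants 15 through 32, when present, get a
#' missing strike index, mirroring the trials for which it was not recorded.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return A data frame with columns `Code`, `Sex`, `Speed`, `Type`, `Age`,
#'   `Height`, `Mass`, `SI`.
#' @export
make_metadata <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  # Beta parameters from mean 0.152, sd 0.195 by moment matching
  mu <- 0.152; v <- 0.195^2
  ab <- mu * (1 - mu) / v - 1
  si <- stats::rbeta(n, mu * ab, (1 - mu) * ab)
  if (n >= 15L) si[15:min(32L, n)] <- NA_real_
  df <- data.frame(
    Code = sprintf("P%04d", seq_len(n)),
    Sex = sample(c("M", "F"), n, replace = TRUE, prob = c(78, 57)),
    Speed = round(rtrunc_pos(n, 2.65, 0.31), 2),
    Type = sample(c("PR", "FX"), n, replace = TRUE),
    Age = round(pmax(18, rnorm(n, 30, 5))),
    Height = round(rnorm(n, 175, 9)),
    Mass = round(rtrunc_pos(n, 69, 11), 1),
    SI = round(si, 3))
  validate_participants(df)
  df
}

#' Synthetic foot geometry and center of pressure at impact
#'
#' Builds a randomly placed and oriented planar foot (heel and toe points)
#' together with a center-of-pressure point at impact located so that the
#' strike-index definition recovers `si_true` exactly: the point lies at
#' `si_true * foot_length` from the heel along the heel-toe axis, plus a
#' small random off-axis offset that orthogonal projection removes.
#'
#' @param foot_length Foot length in meters.
#' @param si_true Target strike index in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with numeric 2-D points `heel`, `toe` and `cop`.
#' @export
make_cop_trace <- function(foot_length, si_true, seed = 1L) {
  if (foot_length <= 0) stop("'foot_length' must be positive", call. = FALSE)
  if (si_true < 0 || si_true > 1) {
    stop("'si_true' must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  heel <- runif(2, -1, 1)
  theta <- runif(1, 0, 2 * pi)
  d <- c(cos(theta), sin(theta))
  perp <- c(-d[2], d[1])
  list(heel = heel,
       toe = heel + foot_length * d,
       cop = heel + si_true * foot_length * d +
         runif(1, -0.1, 0.1) * foot_length * perp)
}

#' Simulate a cohort as a deposited-style file tree
#'
#' Generates `n_participants` ground truths and, for each, the requested
#' number of trials, writing `RAW_EMG_*` and `CYCLE_TIMES_*` files plus a
#' `participants_data.dat` metadata table into `dir`. Per-participant seeds
#' are `seed + participant index`; trial seeds add `100 * trial`.
#'
#' @param n_participants Number of participants.
#' @param dir Output directory (created if missing).
#' @param n_cycles Gait cycles per trial (default 30).
#' @param r True rank (default 4).
#' @param noise_sd Envelope noise level (default 0.1).
#' @param seed Master seed.
#' @param trials_per_participant Trials per participant (default 2).
#' @return Invisibly, the list of ground truths (one per participant).
#' @export
simulate_cohort <- function(n_participants, dir, n_cycles = 30L, r = 4L,
                            noise_sd = 0.1, seed = 1L,
                            trials_per_participant = 2L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gts <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    code <- sprintf("P%04d", i)
    gt <- make_ground_truth(r = r, seed = seed + i, noise_sd = noise_sd)
    gts[[i]] <- gt
    for (j in seq_len(trials_per_participant)) {
      sim <- synthesize_trial(gt, n_cycles = n_cycles,
                              seed = seed + i + 100L * j,
                              participant = code, trial = j)
      write_raw_emg(sim$trial, dir)
      write_cycle_times(sim$ct, dir, code, j)
    }
  }
  meta <- make_metadata(n_participants, seed = seed)
  write_participants(meta, file.path(dir, "participants_data.dat"))
  invisible(gts)
}
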