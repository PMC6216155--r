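#' Conditioned activation matrix
#'
#' The activation matrix V that enters the factorization: one row per muscle
#' (13 rows in canonical order), one column per time-normalized point; with
#' the default grid of 200 points per gait cycle (100 stance + 100 swing),
#' 30 cycles give 6000 columns. All entries are strictly positive: zeros are
#' replaced by the smallest non-zero value during envelope extraction.
#'
#' @param values Numeric matrix, muscles x points; row names must be the 13
#'   muscle abbreviations (set automatically for a bare 13-row matrix).
#' @param points_per_cycle Points per time-normalized cycle (default 200).
#' @return A numeric matrix of class `envelope_matrix` with attributes
#'   `points_per_cycle` and `cycles`.
#' @export
envelope_matrix <- function(values, points_per_cycle = 200L) {
  values <- as.matrix(values)
  if (nrow(values) != length(emg_muscles())) {
    stop("an envelope matrix must have 13 muscle rows", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- emg_muscles()
  } else if (!identical(rownames(values), emg_muscles())) {
    stop("row names must be the 13 canonical muscle abbreviations",
         call. = FALSE)
  }
  if (ncol(values) %% points_per_cycle != 0L) {
    stop("number of columns must be a multiple of 'points_per_cycle'",
         call. = FALSE)
  }
  structure(values,
            points_per_cycle = as.integer(points_per_cycle),
            cycles = ncol(values) %/% points_per_cycle,
            class = "envelope_matrix")
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix> %d muscles x %d points (%d cycles of %d)\n",
              nrow(x), ncol(x), attr(x, "cycles"), attr(x, "points_per_cycle")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Linear envelope of one raw EMG channel
#'
#' Conditions a raw, signed EMG series into its linear envelope: zero-phase
#' high-pass filtering (4th order Butterworth, 50 Hz cut-off, obtained by
#' running a 2nd-order design forward and backward), full-wave
#' rectification, zero-phase low-pass filtering (4th order Butterworth,
#' 20 Hz cut-off, same scheme). Negative values left by the low-pass are set
#' to zero, and every zero entry is then replaced with the smallest non-zero
#' value of the series so the envelope is strictly positive (the
#' factorization requires positive data).
#'
#' @param x Numeric vector, one raw EMG channel (arbitrary units, signed).
#' @param fs Sampling frequency in Hz (default 1000).
#' @param hp_cutoff High-pass cut-off in Hz (default 50).
#' @param lp_cutoff Low-pass cut-off in Hz (default 20).
#' @return Numeric vector of the same length, strictly positive.
#' @export
make_envelope <- function(x, fs = 1000, hp_cutoff = 50, lp_cutoff = 20) {
  if (anyNA(x)) stop("raw EMG contains NA/NaN values", call. = FALSE)
  if (length(x) < 100L) {
    stop(sprintf("series too short for filtering: %d samples (need >= 100)",
                 length(x)), call. = FALSE)
  }
  hp <- signal::butter(2, hp_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(2, lp_cutoff / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  y <- abs(y)
  y <- signal::filtfilt(lp, y)
  y[y < 0] <- 0
  nz <- y[y > 0]
  if (length(nz) == 0L) {
    stop("envelope is identically zero; cannot define a positive floor",
         call. = FALSE)
  }
  y[y == 0] <- min(nz)
  y
}

envelope_channels <- function(trial, fs = 1000, hp_cutoff = 50,
                              lp_cutoff = 20) {
  env <- apply(trial$emg, 2, make_envelope, fs = fs,
               hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff)
  t(env)  # muscles x samples
}

#' Amplitude normalization across a participant's trials
#'
#' Normalizes each muscle's envelope to the maximum activation recorded for
#' that participant across all supplied trials: for every muscle, the
#' envelopes of all trials are divided by the single maximum of that muscle
#' over their concatenation, so the per-muscle global maximum becomes 1.
#'
#' @param envelopes A list of muscles-x-samples envelope matrices (one per
#'   trial, same 13 muscle rows), or a single matrix.
#' @return The input with every muscle row rescaled; a list in, a list out.
#' @export
normalize_amplitude <- function(envelopes) {
  single <- !is.list(envelopes)
  if (single) envelopes <- list(envelopes)
  m <- nrow(envelopes[[1]])
  if (!all(vapply(envelopes, nrow, 0L) == m)) {
    stop("all trials must have the same muscle set", call. = FALSE)
  }
  gmax <- apply(do.call(cbind, envelopes), 1, max)
  flat <- vapply(seq_len(m), function(i) {
    mn <- min(vapply(envelopes, function(e) min(e[i, ]), 0))
    gmax[i] <= mn
  }, logical(1))
  if (any(flat)) {
    warning(sprintf("constant-floor channel(s): %s; left unscaled at <= 1",
                    paste(rownames(envelopes[[1]])[flat], collapse = ", ")),
            call. = FALSE)
    gmax[flat] <- pmax(gmax[flat], 1)
  }
  out <- lapply(envelopes, function(e) e / gmax)
  if (single) out[[1]] else out
}

#' Time normalization of gait cycles to a fixed 200-point grid
#'
#' Resamples each gait cycle of an envelope matrix to 200 points, assigning
#' 100 points to the stance phase (touchdown to touchdown + stance duration)
#' and 100 points to the swing phase (stance end to the next touchdown), by
#' piecewise-linear interpolation on the original sampling grid. Cycles are
#' concatenated column-wise. Each phase grid spans the phase interval
#' including both endpoints, except that the next touchdown (the cycle
#' boundary) is excluded to avoid duplicating the first sample of the
#' following cycle. When the table holds exactly `n_cycles` rows, the swing
#' end of the last cycle has no following touchdown and is estimated as its
#' stance end plus the median swing duration of the preceding cycles.
#'
#' @param env Muscles-x-samples envelope matrix (rows = 13 muscles) on the
#'   raw sampling grid.
#' @param ct A [cycle_times()] table covering the cycles to extract.
#' @param n_cycles Number of gait cycles to keep, from the first (default 30).
#' @param fs Sampling frequency of `env` in Hz (default 1000).
#' @param points_per_phase Points per phase (default 100; 200 per cycle).
#' @return An [envelope_matrix()] with `n_cycles * 2 * points_per_phase`
#'   columns.
#' @export
time_normalize <- function(env, ct, n_cycles = 30L, fs = 1000,
                           points_per_phase = 100L) {
  stopifnot(inherits(ct, "cycle_times"))
  K <- nrow(ct)
  if (K < n_cycles) {
    stop(sprintf("cycle-times table covers %d cycles; %d requested",
                 K, n_cycles), call. = FALSE)
  }
  tmax <- (ncol(env) - 1) / fs
  td <- ct$touchdown
  st <- ct$stance
  ends <- c(td[-1], NA_real_)  # swing end of cycle k = touchdown k+1
  if (is.na(ends[K])) {
    swings <- (td[-1] - td[-K]) - st[-K]
    ends[K] <- td[K] + st[K] + median(swings)
  }
  if (ends[n_cycles] > tmax + 1e-9) {
    complete <- sum(ends <= tmax + 1e-9)
    stop(sprintf("recording holds only %d complete cycles; %d requested",
                 complete, n_cycles), call. = FALSE)
  }
  tgrid <- (seq_len(ncol(env)) - 1) / fs
  p <- points_per_phase
  cols <- lapply(seq_len(n_cycles), function(k) {
    se <- td[k] + st[k]
    qs <- seq(td[k], se, length.out = p)
    qw <- se + (seq_len(p) - 1) / p * (ends[k] - se)
    q <- c(qs, qw)
    t(apply(env, 1, function(ch) approx(tgrid, ch, xout = q)$y))
  })
  envelope_matrix(do.call(cbind, cols), points_per_cycle = 2L * p)
}

#' Full conditioning of one participant's trial pair
#'
#' Convenience wrapper running the complete conditioning chain on the one or
#' two trials of a participant: envelope extraction per channel, joint
#' amplitude normalization (per muscle, across all supplied trials), and
#' time normalization of each trial with its own cycle times.
#'
#' @param trials A list of [emg_trial()] objects (typically the two trials of
#'   one participant).
#' @param cycle_tables A list of [cycle_times()] tables, parallel to
#'   `trials`.
#' @param n_cycles,fs,hp_cutoff,lp_cutoff,points_per_phase Passed on to
#'   [make_envelope()] and [time_normalize()].
#' @return A list of [envelope_matrix()] objects, one per trial.
#' @export
preprocess_trials <- function(trials, cycle_tables, n_cycles = 30L,
                              fs = 1000, hp_cutoff = 50, lp_cutoff = 20,
                              points_per_phase = 100L) {
  stopifnot(length(trials) == length(cycle_tables), length(trials) >= 1L)
  envs <- lapply(trials, envelope_channels, fs = fs,
                 hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff)
  envs <- normalize_amplitude(envs)
  Map(function(e, ct) {
    time_normalize(e, ct, n_cycles = n_cycles, fs = fs,
                   points_per_phase = points_per_phase)
  }, envs, cycle_tables)
}
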