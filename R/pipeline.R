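#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default: filter
#' cut-offs 50 Hz (high-pass) / 20 Hz (low-pass), 100 points per phase
#' (200 per cycle), 30 gait cycles per trial, rank sweep to 10 with 10
#' restarts per rank, convergence window of 20 iterations at a relative
#' R-squared tolerance of 0.01%, model-order MSE threshold 1e-5, and the
#' peak-detection conventions of the classifier.
#'
#' @param fs Sampling frequency, Hz.
#' @param hp_cutoff,lp_cutoff Filter cut-offs, Hz.
#' @param points_per_phase Points per stance/swing phase.
#' @param n_cycles Gait cycles per trial entering the factorization.
#' @param r_max,restarts Rank sweep extent and restarts per rank.
#' @param max_iter,conv_window,conv_tol Multiplicative-update iteration cap,
#'   convergence window (iterations) and relative R-squared tolerance.
#' @param mse_threshold Model-order linear-fit MSE threshold.
#' @param prominence_frac,min_separation,smooth_window Peak-detection
#'   conventions of [classify_primitive()].
#' @param seed Master seed for the whole run.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(fs = 1000, hp_cutoff = 50, lp_cutoff = 20,
                       points_per_phase = 100L, n_cycles = 30L,
                       r_max = 10L, restarts = 10L, max_iter = 1000L,
                       conv_window = 20L, conv_tol = 1e-4,
                       mse_threshold = 1e-5, prominence_frac = 0.1,
                       min_separation = 25L, smooth_window = 5L,
                       seed = 1L) {
  structure(list(fs = fs, hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 points_per_phase = as.integer(points_per_phase),
                 n_cycles = as.integer(n_cycles),
                 r_max = as.integer(r_max), restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter),
                 conv_window = as.integer(conv_window), conv_tol = conv_tol,
                 mse_threshold = mse_threshold,
                 prominence_frac = prominence_frac,
                 min_separation = as.integer(min_separation),
                 smooth_window = as.integer(smooth_window),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full synergy-extraction pipeline over a file tree
#'
#' Discovers every `RAW_EMG_*` file under `input_dir`, pairs it with its
#' `CYCLE_TIMES_*` table (unmatched trials are skipped with a warning) and
#' groups trials by participant. Per participant, the trials are conditioned
#' jointly (amplitude normalization across both trials) but factorized
#' independently: each trial goes through the rank sweep, model-order
#' selection and synergy classification, and its `FILT_EMG_*`, `SYNS_H_*`
#' and `SYNS_W_*` files plus a classification table are written to
#' `output_dir`. A failing trial is logged and skipped, not fatal. Restart
#' seeds derive deterministically from `config$seed`, the participant number
#' and the trial number, so a rerun with the same seed reproduces every
#' number. The configuration is recorded in `output_dir/run_config.txt` for
#' provenance.
#'
#' @param input_dir Directory containing `RAW_EMG_*` and `CYCLE_TIMES_*`
#'   files (for instance from [simulate_cohort()]).
#' @param output_dir Directory for the result tree (created if missing).
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary` (one row per processed trial:
#'   participant, trial, selected rank, R-squared of the accepted solution,
#'   gait-cycle statistics) and `classifications` (per-trial classification
#'   tables). A cohort summary (mean and s.d. of the selected rank) is also
#'   written to `output_dir/cohort_summary.txt`.
#' @export
run_pipeline <- function(input_dir, output_dir, config = run_config()) {
  raw_files <- list.files(input_dir, pattern = "^RAW_EMG_P[0-9]{4}_[0-9]{2}",
                          full.names = TRUE)
  if (length(raw_files) == 0L) {
    stop(sprintf("no RAW_EMG_* files found under %s", input_dir),
         call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  meta <- lapply(raw_files, parse_trial_filename)
  participants <- unique(vapply(meta, `[[`, "", "participant"))
  rows <- list()
  classifications <- list()

  for (p in participants) {
    idx <- which(vapply(meta, `[[`, "", "participant") == p)
    keep <- logical(length(idx))
    cts <- list()
    for (q in seq_along(idx)) {
      tr <- meta[[idx[q]]]$trial
      ct_path <- file.path(input_dir, trial_filename("CYCLE_TIMES", p, tr))
      if (!file.exists(ct_path)) {
        warning(sprintf("no CYCLE_TIMES table for %s trial %02d; skipped",
                        p, tr), call. = FALSE)
        next
      }
      keep[q] <- TRUE
      cts[[length(cts) + 1L]] <- read_cycle_times(ct_path)
    }
    idx <- idx[keep]
    if (length(idx) == 0L) next

    res <- tryCatch({
      trials <- lapply(raw_files[idx], read_raw_emg)
      envs <- preprocess_trials(trials, cts, n_cycles = config$n_cycles,
                                fs = config$fs,
                                hp_cutoff = config$hp_cutoff,
                                lp_cutoff = config$lp_cutoff,
                                points_per_phase = config$points_per_phase)
      pnum <- as.integer(sub("^P", "", p))
      out <- list()
      for (q in seq_along(trials)) {
        tr <- trials[[q]]$trial
        write_filt_emg(envs[[q]], output_dir, p, tr)
        sweep <- rank_sweep(envs[[q]], r_max = config$r_max,
                            restarts = config$restarts,
                            seed = config$seed + 1000L * pnum + 100L * tr,
                            max_iter = config$max_iter,
                            window = config$conv_window,
                            tol = config$conv_tol)
        r_sel <- select_order(sweep, threshold = config$mse_threshold)
        syn <- sweep$solutions[[r_sel]]
        write_synergies(syn, output_dir, p, tr)
        cls <- classify_synergies(syn,
                                  points_per_cycle = 2L * config$points_per_phase,
                                  prominence_frac = config$prominence_frac,
                                  min_separation = config$min_separation,
                                  smooth_window = config$smooth_window)
        write.table(cls,
                    file.path(output_dir,
                              sprintf("CLASS_%s_%02d.dat", p, tr)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        gs <- summarize_cycles(cts[[q]])
        out[[q]] <- list(
          row = data.frame(participant = p, trial = tr,
                           selected_rank = r_sel,
                           r_squared = syn$r_squared,
                           contact_mean_ms = gs$contact_mean,
                           swing_mean_ms = gs$swing_mean,
                           cadence_mean = gs$cadence_mean),
          cls = cls)
      }
      out
    }, error = function(e) {
      warning(sprintf("participant %s failed and was skipped: %s",
                      p, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    for (o in res) {
      rows[[length(rows) + 1L]] <- o$row
      classifications[[sprintf("%s_%02d", o$row$participant, o$row$trial)]] <- o$cls
    }
  }

  if (length(rows) == 0L) {
    stop("no trial could be processed", call. = FALSE)
  }
  summary <- do.call(rbind, rows)

  writeLines(c(
    sprintf("%s = %s", names(unclass(config)),
            vapply(unclass(config), format, "")),
    sprintf("processed_trials = %d", nrow(summary))),
    file.path(output_dir, "run_config.txt"))
  writeLines(c(
    sprintf("trials: %d", nrow(summary)),
    sprintf("selected rank: %.2f +/- %.2f", mean(summary$selected_rank),
            sd(summary$selected_rank)),
    sprintf("reconstruction R^2: %.4f +/- %.4f", mean(summary$r_squared),
            sd(summary$r_squared)),
    sprintf("contact: %.0f ms, swing: %.0f ms, cadence: %.1f steps/min",
            mean(summary$contact_mean_ms), mean(summary$swing_mean_ms),
            mean(summary$cadence_mean))),
    file.path(output_dir, "cohort_summary.txt"))

  invisible(list(summary = summary, classifications = classifications,
                 config = config))
}

#' Plot a synergy set
#'
#' Draws the standard two-panel display of a factorization result: motor
#' modules as per-synergy bar charts of muscle weights and motor primitives
#' as cycle-averaged activation curves over the normalized 200-point gait
#' cycle, with the stance-swing transition marked at midcycle.
#'
#' @param x A [synergy_set()].
#' @param points_per_cycle Points per gait cycle (default 200).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.synergy_set <- function(x, points_per_cycle = 200L, ...) {
  r <- x$r
  old <- graphics::par(mfrow = c(r, 2), mar = c(2.5, 3.5, 1.5, 0.5),
                       mgp = c(2, 0.6, 0))
  on.exit(graphics::par(old))
  for (i in seq_len(r)) {
    graphics::barplot(x$W[, i], las = 2, cex.names = 0.7,
                      main = sprintf("Module %d", i), col = "grey40",
                      border = NA)
    mp <- mean_cycle(x$H[i, ], points_per_cycle)
    graphics::plot(mp, type = "l", lwd = 2, xlab = "", ylab = "activation",
                   main = sprintf("Primitive %d", i))
    graphics::abline(v = points_per_cycle / 2, lty = 2, col = "grey60")
  }
  invisible(x)
}
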