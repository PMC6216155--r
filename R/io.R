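#' File conventions of the running-EMG data set
#'
#' All on-disk artifacts follow the deposited naming pattern
#' `PREFIX_Pxxxx_yy` where `PREFIX` identifies the content
#' (`RAW_EMG`, `FILT_EMG`, `CYCLE_TIMES`, `SYNS_H`, `SYNS_W`), `Pxxxx` is the
#' zero-padded participant code and `yy` the trial number (01 or 02).
#' Files are plain ASCII: tab-delimited on write, any whitespace accepted on
#' read, numeric values serialized to 9 significant digits.
#'
#' @param prefix One of `"RAW_EMG"`, `"FILT_EMG"`, `"CYCLE_TIMES"`,
#'   `"SYNS_H"`, `"SYNS_W"`.
#' @param participant Participant code such as `"P0026"` (or a bare integer).
#' @param trial Trial number, 1 or 2.
#' @return `trial_filename()` returns the file name as a string;
#'   `parse_trial_filename()` returns a list with elements `prefix`,
#'   `participant` and `trial`.
#' @export
#' @examples
#' trial_filename("RAW_EMG", "P0026", 2)
#' parse_trial_filename("RAW_EMG_P0026_02.dat")
trial_filename <- function(prefix, participant, trial) {
  prefix <- match.arg(prefix,
                      c("RAW_EMG", "FILT_EMG", "CYCLE_TIMES", "SYNS_H", "SYNS_W"))
  if (is.numeric(participant)) {
    participant <- sprintf("P%04d", as.integer(participant))
  }
  if (!grepl("^P[0-9]{4}$", participant)) {
    stop("'participant' must be a token like \"P0026\"", call. = FALSE)
  }
  sprintf("%s_%s_%02d.dat", prefix, participant, as.integer(trial))
}

#' @rdname trial_filename
#' @param path File name or path following the naming pattern.
#' @export
parse_trial_filename <- function(path) {
  base <- basename(path)
  pat <- "^(RAW_EMG|FILT_EMG|CYCLE_TIMES|SYNS_H|SYNS_W)_(P[0-9]{4})_([0-9]{2})(\\.[A-Za-z0-9]+)?$"
  m <- regmatches(base, regexec(pat, base))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("file name '%s' does not follow the PREFIX_Pxxxx_yy pattern", base),
         call. = FALSE)
  }
  list(prefix = m[2], participant = m[3], trial = as.integer(m[4]))
}

fmt9 <- function(x) signif(x, 9)

read_ascii_table <- function(path, header, row.names = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  # tab-delimited files keep empty fields (e.g. a missing SI); fall back to
  # any-whitespace separation otherwise
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ""
  if (is.null(row.names)) {
    read.table(path, header = header, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE)
  } else {
    read.table(path, header = header, sep = sep, row.names = row.names,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
}

check_numeric_columns <- function(df, path) {
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) & !is.na(df[[j]]))
      row <- if (length(bad)) bad[1] else 1L
      stop(sprintf("non-numeric value in column '%s' at data row %d of %s",
                   names(df)[j], row, basename(path)), call. = FALSE)
    }
  }
  invisible(df)
}

# raw EMG trials --------------------------------------------------------

#' Construct a raw EMG trial
#'
#' A raw trial holds the incremental time vector (seconds, 1 kHz sampling)
#' and the 13 signed EMG channels of one 30-s acquisition.
#'
#' @param time Numeric vector of sample times in seconds, 1-ms steps.
#' @param emg Numeric matrix, one column per muscle; column names must be the
#'   13 abbreviations of [emg_muscles()] in that order.
#' @param participant Participant code such as `"P0026"`.
#' @param trial Trial number (1 or 2).
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(time, emg, participant = "P0001", trial = 1L) {
  emg <- as.matrix(emg)
  if (length(time) != nrow(emg)) {
    stop("'time' and 'emg' must have the same number of samples", call. = FALSE)
  }
  if (!identical(colnames(emg), emg_muscles())) {
    stop("'emg' must have the 13 muscle columns ",
         paste(emg_muscles(), collapse = ", "), " in canonical order",
         call. = FALSE)
  }
  structure(list(time = as.numeric(time), emg = emg,
                 participant = participant, trial = as.integer(trial)),
            class = "emg_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial> %s trial %02d: %d samples x %d muscles (%.1f s)\n",
              x$participant, x$trial, nrow(x$emg), ncol(x$emg),
              diff(range(x$time))))
  invisible(x)
}

#' Read and write raw EMG trials
#'
#' Raw trials are serialized as ASCII tables with 14 columns: incremental
#' time in seconds followed by the 13 muscle channels. A canonical 30-s trial
#' has 30000 rows. Participant and trial number are parsed from the file
#' name (`RAW_EMG_Pxxxx_yy`).
#'
#' @param path Path to a `RAW_EMG_*` file.
#' @return `read_raw_emg()` returns an [emg_trial()]; `write_raw_emg()`
#'   returns the path written, invisibly.
#' @export
read_raw_emg <- function(path) {
  meta <- parse_trial_filename(path)
  df <- read_ascii_table(path, header = TRUE)
  expected <- c("time", emg_muscles())
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing)) {
    stop(sprintf("missing column(s) in %s: %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(extra)) {
    stop(sprintf("unexpected column(s) in %s: %s", basename(path),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  check_numeric_columns(df, path)
  emg_trial(df$time, as.matrix(df[emg_muscles()]),
            participant = meta$participant, trial = meta$trial)
}

#' @rdname read_raw_emg
#' @param x An [emg_trial()].
#' @param dir Output directory.
#' @export
write_raw_emg <- function(x, dir) {
  stopifnot(inherits(x, "emg_trial"))
  path <- file.path(dir, trial_filename("RAW_EMG", x$participant, x$trial))
  df <- data.frame(time = fmt9(x$time), fmt9(x$emg), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# cycle times -----------------------------------------------------------

#' Construct a gait-cycle times table
#'
#' One row per gait cycle: the touchdown incremental time (seconds from the
#' start of the recording) and the duration of the stance phase (seconds).
#' Touchdowns must be strictly increasing and each stance must fit inside
#' its cycle (shorter than the interval to the next touchdown).
#'
#' @param touchdown Numeric vector of touchdown times, seconds.
#' @param stance Numeric vector of stance durations, seconds.
#' @return A data frame of class `cycle_times` with columns `touchdown` and
#'   `stance`.
#' @export
cycle_times <- function(touchdown, stance) {
  if (length(touchdown) != length(stance)) {
    stop("'touchdown' and 'stance' must have equal length", call. = FALSE)
  }
  if (any(diff(touchdown) <= 0)) {
    stop("touchdown times must be strictly increasing", call. = FALSE)
  }
  if (any(stance <= 0)) {
    stop("stance durations must be positive", call. = FALSE)
  }
  n <- length(touchdown)
  if (n > 1L) {
    cyc <- diff(touchdown)
    bad <- which(stance[-n] >= cyc)
    if (length(bad)) {
      stop(sprintf("stance duration of cycle %d (%.3f s) is not shorter than its cycle (%.3f s)",
                   bad[1], stance[bad[1]], cyc[bad[1]]), call. = FALSE)
    }
  }
  structure(data.frame(touchdown = as.numeric(touchdown),
                       stance = as.numeric(stance)),
            class = c("cycle_times", "data.frame"))
}

#' Read and write gait-cycle breakdown tables
#'
#' `CYCLE_TIMES_*` files are two-column ASCII tables, one row per gait cycle
#' (30 rows for a canonical trial): touchdown incremental time and stance
#' duration, both in seconds.
#'
#' @param path Path to a `CYCLE_TIMES_*` file.
#' @return `read_cycle_times()` returns a [cycle_times()] table;
#'   `write_cycle_times()` returns the path written, invisibly.
#' @export
read_cycle_times <- function(path) {
  df <- read_ascii_table(path, header = TRUE)
  if (ncol(df) != 2L) {
    stop(sprintf("%s must have exactly two columns, found %d",
                 basename(path), ncol(df)), call. = FALSE)
  }
  check_numeric_columns(df, path)
  cycle_times(df[[1]], df[[2]])
}

#' @rdname read_cycle_times
#' @param ct A [cycle_times()] table.
#' @param dir Output directory.
#' @param participant,trial Identify the trial for the file name.
#' @export
write_cycle_times <- function(ct, dir, participant, trial) {
  stopifnot(inherits(ct, "cycle_times"))
  path <- file.path(dir, trial_filename("CYCLE_TIMES", participant, trial))
  df <- data.frame(touchdown = fmt9(ct$touchdown), stance = fmt9(ct$stance))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# participants metadata -------------------------------------------------

#' Read and write the participants metadata table
#'
#' The metadata table (`participants_data.dat`) has one row per participant
#' with columns `Code`, `Sex` (M/F), `Speed` (m/s), `Type` (PR for preferred
#' or FX for fixed speed), `Age` (years), `Height` (cm), `Mass` (kg) and
#' `SI`, the strike index in `[0, 1]`. A missing strike index (not recorded
#' for some participants) is encoded as an empty field or `NA` and read back
#' as `NA`.
#'
#' @param path Path of the metadata file.
#' @return `read_participants()` returns a data frame with the eight columns
#'   above; `write_participants()` returns the path written, invisibly.
#' @export
read_participants <- function(path) {
  df <- read_ascii_table(path, header = TRUE)
  expected <- c("Code", "Sex", "Speed", "Type", "Age", "Height", "Mass", "SI")
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s) in %s: %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[expected]
  df$SI <- suppressWarnings(as.numeric(df$SI))
  validate_participants(df)
  df
}

validate_participants <- function(df) {
  if (any(df$Speed <= 0)) {
    stop("participant speed must be positive", call. = FALSE)
  }
  si <- df$SI[!is.na(df$SI)]
  if (any(si < 0 | si > 1)) {
    stop("strike index (SI) must lie in [0, 1]", call. = FALSE)
  }
  if (!all(df$Sex %in% c("M", "F"))) {
    stop("Sex must be 'M' or 'F'", call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_participants
#' @param df Participants data frame with the eight canonical columns.
#' @export
write_participants <- function(df, path) {
  validate_participants(df)
  out <- df
  num <- c("Speed", "Age", "Height", "Mass", "SI")
  out[num] <- lapply(out[num], fmt9)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

# synergies -------------------------------------------------------------

#' Read and write extracted synergies
#'
#' A factorization result is stored as two ASCII files: the motor primitives
#' `SYNS_H_*` (one row per synergy, named `Syn1` ... `Synr`, one column per
#' time-normalized point) and the motor modules `SYNS_W_*` (13 rows named by
#' muscle, one column per synergy).
#'
#' @param syn A [synergy_set()] (or any list with numeric matrices `W`
#'   and `H`).
#' @param dir Output directory.
#' @param participant,trial Identify the trial for the file names.
#' @return `write_synergies()` returns a character vector with the primitives
#'   and modules paths, invisibly. `read_synergies()` returns a list with
#'   matrices `W` (13 x r) and `H` (r x n) and the rank `r`.
#' @export
write_synergies <- function(syn, dir, participant, trial) {
  W <- syn$W
  H <- syn$H
  stopifnot(is.matrix(W), is.matrix(H), nrow(H) == ncol(W))
  r <- ncol(W)
  path_h <- file.path(dir, trial_filename("SYNS_H", participant, trial))
  path_w <- file.path(dir, trial_filename("SYNS_W", participant, trial))
  Hn <- fmt9(H)
  rownames(Hn) <- sprintf("Syn%d", seq_len(r))
  write.table(Hn, path_h, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = FALSE)
  Wn <- fmt9(W)
  rownames(Wn) <- emg_muscles()
  colnames(Wn) <- sprintf("Syn%d", seq_len(r))
  write.table(Wn, path_w, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(c(primitives = path_h, modules = path_w))
}

#' @rdname write_synergies
#' @param path_h,path_w Paths to the primitives (`SYNS_H_*`) and modules
#'   (`SYNS_W_*`) files.
#' @export
read_synergies <- function(path_h, path_w) {
  H <- as.matrix(read_ascii_table(path_h, header = FALSE, row.names = 1))
  W <- as.matrix(read_ascii_table(path_w, header = TRUE, row.names = 1))
  colnames(H) <- NULL
  if (!identical(rownames(W), emg_muscles())) {
    stop("modules file must have the 13 canonical muscle rows", call. = FALSE)
  }
  if (ncol(W) != nrow(H)) {
    stop("modules and primitives disagree on the number of synergies",
         call. = FALSE)
  }
  list(W = W, H = H, r = ncol(W))
}

# filtered (conditioned, time-normalized) EMG ---------------------------

#' Read and write conditioned, time-normalized EMG
#'
#' `FILT_EMG_*` files hold the activation matrix after envelope extraction,
#' amplitude normalization and 200-point time normalization: one row per
#' time-normalized point (cycles concatenated), one column per muscle.
#'
#' @param env An [envelope_matrix()].
#' @param dir Output directory.
#' @param participant,trial Identify the trial for the file name.
#' @return `write_filt_emg()` returns the path written, invisibly;
#'   `read_filt_emg()` returns an [envelope_matrix()].
#' @export
write_filt_emg <- function(env, dir, participant, trial) {
  stopifnot(inherits(env, "envelope_matrix"))
  path <- file.path(dir, trial_filename("FILT_EMG", participant, trial))
  write.table(fmt9(t(unclass(env))), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_filt_emg
#' @param path Path to a `FILT_EMG_*` file.
#' @param points_per_cycle Points per time-normalized gait cycle (default 200).
#' @export
read_filt_emg <- function(path, points_per_cycle = 200L) {
  df <- read_ascii_table(path, header = TRUE)
  if (!identical(names(df), emg_muscles())) {
    stop("FILT_EMG file must have the 13 canonical muscle columns",
         call. = FALSE)
  }
  check_numeric_columns(df, path)
  envelope_matrix(t(as.matrix(df)), points_per_cycle = points_per_cycle)
}
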