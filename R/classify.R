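#' Cycle-averaged motor primitive
#'
#' Averages a concatenated-cycles primitive row point-wise across gait
#' cycles, yielding the mean activation over the normalized 200-point cycle.
#'
#' @param x Numeric vector whose length is a multiple of `points_per_cycle`.
#' @param points_per_cycle Points per gait cycle (default 200).
#' @return Numeric vector of length `points_per_cycle`.
#' @export
mean_cycle <- function(x, points_per_cycle = 200L) {
  if (length(x) %% points_per_cycle != 0L) {
    stop(sprintf("length %d is not a multiple of %d points per cycle",
                 length(x), points_per_cycle), call. = FALSE)
  }
  rowMeans(matrix(x, nrow = points_per_cycle))
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  half <- k %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

find_major_peaks <- function(y, prominence_frac, min_separation) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) cand <- c(1L, cand)
  if (y[n] > y[n - 1L]) cand <- c(cand, n)
  floor_h <- prominence_frac * max(y)
  cand <- cand[y[cand] >= floor_h]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(p - kept) >= min_separation)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Classify a motor primitive as fundamental or combined
#'
#' Counts the major activation peaks of a cycle-averaged motor primitive:
#' a primitive with a single major peak defines a fundamental synergy, one
#' with two or more peaks a combined synergy (a blend of fundamentals). The
#' primitive is lightly smoothed with a centered moving average before peak
#' detection; a local maximum counts as major when its height reaches
#' `prominence_frac` of the primitive's maximum, and peaks closer together
#' than `min_separation` points are merged into the highest one. The cycle
#' start is a true boundary (touchdown): no circular wrap is applied.
#'
#' @param mean_primitive Non-negative numeric vector (one normalized cycle,
#'   typically 200 points).
#' @param prominence_frac Height floor as a fraction of the maximum
#'   (default 0.1).
#' @param min_separation Minimum distance between distinct peaks in points
#'   (default 25, i.e. 12.5% of a 200-point cycle).
#' @param smooth_window Width of the pre-smoothing moving average in points
#'   (default 5).
#' @return A list with `kind` (`"fundamental"` or `"combined"`),
#'   `peak_count`, and `peaks` (sorted peak locations, 1-based points).
#' @export
classify_primitive <- function(mean_primitive, prominence_frac = 0.1,
                               min_separation = 25L, smooth_window = 5L) {
  y <- as.numeric(mean_primitive)
  if (any(y < 0)) stop("a motor primitive must be non-negative", call. = FALSE)
  if (diff(range(y)) == 0) {
    stop("constant primitive: no peaks are definable", call. = FALSE)
  }
  ys <- moving_average(y, smooth_window)
  peaks <- find_major_peaks(ys, prominence_frac, min_separation)
  if (length(peaks) == 0L) peaks <- which.max(ys)
  list(kind = if (length(peaks) == 1L) "fundamental" else "combined",
       peak_count = length(peaks),
       peaks = peaks)
}

#' Functional phase labels for classified synergies
#'
#' Assigns each fundamental synergy a functional label from the quadrant of
#' the 200-point gait cycle holding its main (highest) peak: points 1-50
#' weight acceptance (early stance), 51-100 propulsion (late stance),
#' 101-150 early swing, 151-200 late swing. Combined synergies receive the
#' label `"none"`.
#'
#' @param classified A list of results from [classify_primitive()]; an
#'   optional `main_peak` element (set by [classify_synergies()]) marks the
#'   highest peak, otherwise the first peak location is used.
#' @param points_per_cycle Points per cycle (default 200).
#' @return Character vector of labels, one per synergy.
#' @export
label_synergies <- function(classified, points_per_cycle = 200L) {
  quadrants <- c("weight-acceptance", "propulsion", "early-swing", "late-swing")
  vapply(classified, function(cl) {
    if (cl$kind != "fundamental") return("none")
    p <- if (!is.null(cl$main_peak)) cl$main_peak else cl$peaks[1]
    q <- min(4L, 1L + (p - 1L) %/% (points_per_cycle %/% 4L))
    quadrants[q]
  }, character(1))
}

#' Classify every synergy of a factorization result
#'
#' Runs the full classification chain on a [synergy_set()]: each motor
#' primitive row is cycle-averaged, classified as fundamental or combined by
#' its major-peak count, and labeled with the functional gait-cycle phase of
#' its main peak.
#'
#' @param syn A [synergy_set()] (or any list with a primitives matrix `H`).
#' @param points_per_cycle Points per gait cycle (default 200).
#' @param ... Passed on to [classify_primitive()].
#' @return A data frame with columns `synergy`, `kind`, `peak_count`,
#'   `peak_location` (main peak, 1-based point) and `label`.
#' @export
classify_synergies <- function(syn, points_per_cycle = 200L, ...) {
  H <- syn$H
  cls <- lapply(seq_len(nrow(H)), function(i) {
    mp <- mean_cycle(H[i, ], points_per_cycle)
    cl <- classify_primitive(mp, ...)
    ysm <- moving_average(as.numeric(mp), 5L)
    cl$main_peak <- cl$peaks[which.max(ysm[cl$peaks])]
    cl
  })
  data.frame(synergy = seq_len(nrow(H)),
             kind = vapply(cls, `[[`, "", "kind"),
             peak_count = vapply(cls, function(x) x$peak_count, 0L),
             peak_location = vapply(cls, function(x) x$main_peak, 0L),
             label = label_synergies(cls, points_per_cycle))
}
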