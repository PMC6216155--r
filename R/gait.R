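#' Gait-cycle summary statistics
#'
#' Summarizes a gait-cycle times table: per cycle, the contact (stance)
#' time is read directly, the cycle duration is the interval to the next
#' touchdown, the swing time is cycle minus contact, and the cadence is
#' `2 * 60 / cycle duration` steps per minute (both feet counted: one
#' single-limb gait cycle contains two steps). Means and standard deviations
#' are taken over cycles; swing and cadence use the cycles with a following
#' touchdown (one fewer than the table rows).
#'
#' @param ct A [cycle_times()] table with at least two rows.
#' @return An object of class `gait_summary`: a list with `contact_mean`,
#'   `contact_sd`, `swing_mean`, `swing_sd` (milliseconds), `cadence_mean`,
#'   `cadence_sd` (steps/min) and `n_cycles`.
#' @export
#' @examples
#' ct <- cycle_times(seq(0, 7.4, by = 0.74), rep(0.288, 11))
#' summarize_cycles(ct)
summarize_cycles <- function(ct) {
  stopifnot(inherits(ct, "cycle_times"))
  K <- nrow(ct)
  if (K < 2L) {
    stop("at least two touchdowns are needed to measure cycle durations",
         call. = FALSE)
  }
  contact <- ct$stance * 1000                    # ms
  cyc <- diff(ct$touchdown)                      # s, K - 1 complete cycles
  swing <- cyc * 1000 - contact[-K]              # ms
  cadence <- 2 * 60 / cyc                        # steps/min
  structure(list(contact_mean = mean(contact), contact_sd = sd(contact),
                 swing_mean = mean(swing), swing_sd = sd(swing),
                 cadence_mean = mean(cadence), cadence_sd = sd(cadence),
                 n_cycles = K),
            class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf("<gait_summary> %d cycles\n", x$n_cycles))
  cat(sprintf("  contact %.0f +/- %.0f ms, swing %.0f +/- %.0f ms, cadence %.1f +/- %.1f steps/min\n",
              x$contact_mean, x$contact_sd, x$swing_mean, x$swing_sd,
              x$cadence_mean, x$cadence_sd))
  invisible(x)
}

#' Strike index from foot geometry and center of pressure at impact
#'
#' The strike index is the distance from the heel to the center of pressure
#' at impact, along the heel-toe axis, relative to total foot length — a
#' dimensionless value in `[0, 1]` (0 = impact at the heel, 1 = at the toe).
#' A center of pressure lying off the axis is orthogonally projected onto
#' it; the result is clamped to `[0, 1]`.
#'
#' @param heel,toe,cop Numeric coordinate vectors (same length, typically
#'   2-D, any planar units).
#' @return Scalar strike index in `[0, 1]`.
#' @export
#' @examples
#' strike_index(c(0, 0), c(0.25, 0), c(0.05, 0))  # 0.2
strike_index <- function(heel, toe, cop) {
  heel <- as.numeric(heel); toe <- as.numeric(toe); cop <- as.numeric(cop)
  if (length(heel) != length(toe) || length(heel) != length(cop)) {
    stop("'heel', 'toe' and 'cop' must have the same dimension", call. = FALSE)
  }
  axis <- toe - heel
  L <- sqrt(sum(axis^2))
  if (L == 0) stop("foot length is zero: heel and toe coincide", call. = FALSE)
  s <- sum((cop - heel) * axis) / L^2
  min(1, max(0, s))
}

#' Foot strike pattern from the strike index
#'
#' Classifies the foot strike pattern: a strike index strictly below 0.333
#' denotes a rearfoot strike; 0.333 and above a midfoot/forefoot strike.
#'
#' @param si Strike index in `[0, 1]`.
#' @return `"rearfoot"` or `"midfoot-forefoot"`.
#' @export
#' @examples
#' foot_strike_class(0.152)
foot_strike_class <- function(si) {
  stop_if_not_scalar_number(si, "si")
  if (si < 0 || si > 1) {
    stop("strike index must lie in [0, 1]", call. = FALSE)
  }
  if (si < 0.333) "rearfoot" else "midfoot-forefoot"
}
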