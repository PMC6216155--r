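#' Mean squared error of a straight-line fit
#'
#' Fits an ordinary least-squares line through the supplied
#' (rank, R-squared) points and returns the mean of the squared residuals.
#' This is the elementary step of the model-order selection loop.
#'
#' @param r Numeric vector of ranks (x-coordinates).
#' @param r2 Numeric vector of R-squared values (y-coordinates), same length.
#' @return Scalar mean squared residual.
#' @export
#' @examples
#' linear_fit_mse(1:3, c(0, 1, 0))  # 2/9
linear_fit_mse <- function(r, r2) {
  if (length(r) != length(r2)) {
    stop("'r' and 'r2' must have equal length", call. = FALSE)
  }
  if (length(r) < 2L) {
    stop("at least two points are needed for a linear fit", call. = FALSE)
  }
  fit <- lm(r2 ~ r)
  mean(fit$residuals^2)
}

#' Minimum number of synergies from the R-squared-versus-rank curve
#'
#' Implements the iterative linear-fit criterion: fit a straight line to the
#' current R-squared-versus-rank curve and compute the mean squared error of
#' the fit; if it is below `threshold` stop, otherwise drop the lowest-rank
#' point and repeat; also stop when only two points remain. The selected
#' model order is the rank of the first point of the final (most linear)
#' curve segment — the rank at which reconstruction quality stops improving
#' faster than linearly. This avoids placing an arbitrary threshold on the
#' reconstruction R-squared itself.
#'
#' @param curve A `rank_curve` from [rank_sweep()], or a numeric vector of
#'   best R-squared values for ranks `1, 2, ...`.
#' @param threshold Mean-squared-error threshold (default `1e-5`); the loop
#'   stops when the MSE falls strictly below it.
#' @return The selected rank (integer).
#' @export
select_order <- function(curve, threshold = 1e-5) {
  if (inherits(curve, "rank_curve")) {
    r <- curve$r_values
    r2 <- curve$best_r2
  } else {
    r2 <- as.numeric(curve)
    r <- seq_along(r2)
  }
  if (length(r) < 2L) {
    stop("the curve must contain at least two points", call. = FALSE)
  }
  repeat {
    if (linear_fit_mse(r, r2) < threshold || length(r) == 2L) {
      return(as.integer(r[1]))
    }
    r <- r[-1]
    r2 <- r2[-1]
  }
}
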