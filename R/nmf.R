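#' Coefficient of determination between data and reconstruction
#'
#' `R^2 = 1 - SSE / SST`, with `SSE` the sum of squared entry-wise
#' differences between `V` and `V_R`, and `SST` the total sum of squares of
#' `V` about its grand mean. Used both as the quality-of-reconstruction
#' measure and inside the factorization's convergence rule.
#'
#' @param V Numeric matrix of observed activations.
#' @param V_R Numeric matrix of the same shape (the reconstruction).
#' @return A scalar `<= 1`.
#' @export
#' @examples
#' V <- matrix(c(1, 3, 2, 4), 2)
#' r_squared(V, V)  # 1
r_squared <- function(V, V_R) {
  V <- as.matrix(V); V_R <- as.matrix(V_R)
  if (!all(dim(V) == dim(V_R))) {
    stop("'V' and 'V_R' must have the same shape", call. = FALSE)
  }
  sst <- sum((V - mean(V))^2)
  if (sst == 0) {
    stop("'V' is constant: total sum of squares is zero", call. = FALSE)
  }
  1 - sum((V - V_R)^2) / sst
}

#' A factorization result (one synergy set)
#'
#' Bundles the outcome of one non-negative matrix factorization: the motor
#' modules `W` (muscles x rank, time-invariant weights), the motor
#' primitives `H` (rank x points, time-dependent activations), the rank,
#' the reconstruction R-squared, the iteration count and the seed used for
#' the random initialization.
#'
#' @param W,H Non-negative matrices with `ncol(W) == nrow(H)`.
#' @param r_squared Reconstruction R-squared in `[0, 1]`.
#' @param iterations Number of multiplicative-update iterations performed.
#' @param seed Integer seed of the initialization.
#' @param r2_trace Optional per-iteration R-squared trace.
#' @return An object of class `synergy_set`.
#' @export
synergy_set <- function(W, H, r_squared, iterations, seed = NA_integer_,
                        r2_trace = NULL) {
  stopifnot(is.matrix(W), is.matrix(H), ncol(W) == nrow(H))
  if (min(W) < 0 || min(H) < 0) {
    stop("'W' and 'H' must be non-negative", call. = FALSE)
  }
  structure(list(W = W, H = H, r = ncol(W), r_squared = r_squared,
                 iterations = as.integer(iterations), seed = seed,
                 r2_trace = r2_trace),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> rank %d: W %dx%d, H %dx%d; R^2 = %.4f (%d iterations)\n",
              x$r, nrow(x$W), ncol(x$W), nrow(x$H), ncol(x$H),
              x$r_squared, x$iterations))
  invisible(x)
}

#' Non-negative matrix factorization by Gaussian multiplicative updates
#'
#' Factorizes the strictly positive activation matrix `V` (muscles x points)
#' into non-negative motor modules `W` and motor primitives `H` so that
#' `V ~ W %*% H`, by alternating multiplicative updates: per iteration, first
#' `H <- H * (W'V) / (W'W H)`, then `W <- W * (V H') / (W H H')` (entry-wise
#' products and quotients; denominators floored at 1e-12). `W` and `H` start
#' from seeded i.i.d. uniform draws on (0, 1). Convergence is declared when
#' the spread of the reconstruction R-squared over the last `window`
#' iterations drops below `tol` (a relative 0.01% by default) of its current
#' value, or at `max_iter`.
#'
#' @param V Numeric matrix (or [envelope_matrix()]), strictly positive.
#' @param r Rank: the number of synergies, `1 <= r <= nrow(V)`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap (default 1000; convergence normally fires
#'   first).
#' @param window Width of the convergence window in iterations (default 20).
#' @param tol Relative R-squared spread declaring convergence (default 1e-4,
#'   i.e. 0.01%).
#' @return A [synergy_set()].
#' @export
nmf_factorize <- function(V, r, seed = 1L, max_iter = 1000L,
                          window = 20L, tol = 1e-4) {
  V <- unclass(as.matrix(V))
  m <- nrow(V)
  if (r < 1L || r != round(r)) stop("'r' must be a positive integer", call. = FALSE)
  if (r > m) {
    stop(sprintf("rank r = %d exceeds the number of muscles m = %d", r, m),
         call. = FALSE)
  }
  if (min(V) < 0) stop("'V' must be non-negative", call. = FALSE)
  if (sum((V - mean(V))^2) == 0) {
    stop("'V' is constant: R^2 is undefined", call. = FALSE)
  }
  set.seed(seed)
  W0 <- matrix(runif(m * r), m, r)
  H0 <- matrix(runif(r * ncol(V)), r, ncol(V))
  fit <- nmf_mu_cpp(V, W0, H0, as.integer(max_iter), as.integer(window), tol)
  W <- fit$W
  rownames(W) <- rownames(V)
  synergy_set(W, fit$H, r_squared = fit$r_squared,
              iterations = fit$iterations, seed = seed,
              r2_trace = fit$r2_trace)
}

#' Rank sweep with random restarts
#'
#' Runs the factorization for every rank from 1 to `r_max`, with `restarts`
#' independently seeded random initializations per rank (restart seeds are
#' `seed + 1`, `seed + 2`, ... in rank-major order), keeping for each rank
#' the solution with the highest reconstruction R-squared. The resulting
#' R-squared-versus-rank curve is the input of [select_order()].
#'
#' @param V Strictly positive activation matrix (muscles x points).
#' @param r_max Largest rank to try (default 10; must stay below the number
#'   of muscles).
#' @param restarts Random restarts per rank (default 10).
#' @param seed Master seed; restart seeds are derived from it.
#' @param ... Passed on to [nmf_factorize()] (`max_iter`, `window`, `tol`).
#' @return An object of class `rank_curve`: a list with `r_values`,
#'   `best_r2` and `solutions` (the best [synergy_set()] per rank).
#' @export
rank_sweep <- function(V, r_max = 10L, restarts = 10L, seed = 1L, ...) {
  m <- nrow(V)
  if (r_max >= m) {
    stop(sprintf("'r_max' (%d) must be smaller than the number of muscles (%d)",
                 r_max, m), call. = FALSE)
  }
  solutions <- vector("list", r_max)
  best_r2 <- numeric(r_max)
  k <- 0L
  for (r in seq_len(r_max)) {
    best <- NULL
    for (j in seq_len(restarts)) {
      k <- k + 1L
      fit <- nmf_factorize(V, r, seed = seed + k, ...)
      if (is.null(best) || fit$r_squared > best$r_squared) best <- fit
    }
    solutions[[r]] <- best
    best_r2[r] <- best$r_squared
  }
  structure(list(r_values = seq_len(r_max), best_r2 = best_r2,
                 solutions = solutions),
            class = "rank_curve")
}

#' @export
print.rank_curve <- function(x, ...) {
  cat(sprintf("<rank_curve> best-of-restarts R^2 for ranks 1..%d\n",
              max(x$r_values)))
  print(round(stats::setNames(x$best_r2, x$r_values), 4))
  invisible(x)
}

#' Match an estimated synergy set against a reference
#'
#' Pairs estimated module columns with reference module columns by greedy
#' best cosine similarity (highest similarity first, each column used once),
#' resolving the permutation and scale ambiguity inherent to the
#' factorization. Useful for validating recovery on synthetic data.
#'
#' @param W_est,W_ref Module matrices with the same number of rows; `W_ref`
#'   must not have more columns than `W_est`.
#' @return A data frame with one row per reference column: `ref`, `est`
#'   (matched estimated column) and `cosine` similarity.
#' @export
match_synergies <- function(W_est, W_ref) {
  stopifnot(nrow(W_est) == nrow(W_ref), ncol(W_ref) <= ncol(W_est))
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(seq_len(ncol(W_ref)), seq_len(ncol(W_est)),
               Vectorize(function(i, j) cs(W_ref[, i], W_est[, j])))
  pairs <- data.frame(ref = integer(0), est = integer(0), cosine = numeric(0))
  free_ref <- seq_len(ncol(W_ref))
  free_est <- seq_len(ncol(W_est))
  while (length(free_ref)) {
    sub <- sim[free_ref, free_est, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(ref = free_ref[ij[1]],
                                     est = free_est[ij[2]],
                                     cosine = sub[ij[1], ij[2]]))
    free_ref <- free_ref[-ij[1]]
    free_est <- free_est[-ij[2]]
  }
  pairs[order(pairs$ref), ]
}
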