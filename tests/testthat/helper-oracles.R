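# Independent reference implementations used as oracles. These deliberately
# share no code with the package: filters are derived from the analog
# Butterworth prototype by hand, NMF is the naive full-matrix update loop,
# and the model-order procedure is enacted directly on the curve.

# 2nd-order Butterworth coefficients via bilinear transform; W is the
# cut-off as a fraction of Nyquist.
oracle_butter2 <- function(W, type = c("low", "high")) {
  type <- match.arg(type)
  K <- tan(pi * W / 2)
  D <- K^2 + sqrt(2) * K + 1
  a <- c(1, 2 * (K^2 - 1) / D, (K^2 - sqrt(2) * K + 1) / D)
  b <- if (type == "low") c(K^2, 2 * K^2, K^2) / D else c(1, -2, 1) / D
  list(b = b, a = a)
}

# direct-form difference equation, zero initial conditions
oracle_filter <- function(b, a, x) {
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    y[n] <- b[1] * x[n] +
      (if (n > 1) b[2] * x[n - 1] - a[2] * y[n - 1] else 0) +
      (if (n > 2) b[3] * x[n - 2] - a[3] * y[n - 2] else 0)
  }
  y
}

# zero-phase application: zero-pad, forward pass, reversed pass
oracle_filtfilt <- function(b, a, x) {
  y <- oracle_filter(b, a, c(x, numeric(2 * max(length(a), length(b)))))
  rev(oracle_filter(b, a, rev(y)))[seq_along(x)]
}

# the full envelope cascade: HP 50 Hz -> rectify -> LP 20 Hz -> floors
oracle_envelope <- function(x, fs = 1000, hp = 50, lp = 20) {
  ch <- oracle_butter2(hp / (fs / 2), "high")
  cl <- oracle_butter2(lp / (fs / 2), "low")
  y <- oracle_filtfilt(cl$b, cl$a, abs(oracle_filtfilt(ch$b, ch$a, x)))
  y[y < 0] <- 0
  y[y == 0] <- min(y[y > 0])
  y
}

# naive multiplicative-update NMF, full matrices formed every iteration
oracle_nmf <- function(V, r, seed, max_iter = 5000) {
  set.seed(seed)
  W <- matrix(runif(nrow(V) * r), nrow(V), r)
  H <- matrix(runif(r * ncol(V)), r, ncol(V))
  prev <- Inf
  sse <- NA_real_
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / pmax(t(W) %*% W %*% H, 1e-12)
    W <- W * (V %*% t(H)) / pmax(W %*% H %*% t(H), 1e-12)
    sse <- sum((V - W %*% H)^2)
    if (abs(prev - sse) < 1e-13 * sse) break
    prev <- sse
  }
  list(W = W, H = H, frob = sqrt(sse))
}

# direct enactment of the drop-and-refit model-order loop
oracle_select_order <- function(r2, threshold = 1e-5) {
  r <- seq_along(r2)
  y <- r2
  repeat {
    xb <- mean(r); yb <- mean(y)
    slope <- sum((r - xb) * (y - yb)) / sum((r - xb)^2)
    mse <- mean((y - (yb + slope * (r - xb)))^2)
    if (mse < threshold || length(r) == 2L) return(r[1])
    r <- r[-1]; y <- y[-1]
  }
}

# direct arithmetic on a cycle table
oracle_gait <- function(touchdown, stance) {
  K <- length(touchdown)
  cyc <- touchdown[-1] - touchdown[-K]
  list(contact_mean = mean(stance) * 1000,
       swing_mean = mean(cyc * 1000 - stance[-K] * 1000),
       cadence_mean = mean(120 / cyc))
}

# Frobenius reconstruction error of a fitted synergy set
frob_err <- function(V, fit) sqrt(sum((V - fit$W %*% fit$H)^2))
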