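# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive loops and definitions written from first
# principles, no shared code with the package internals.

# O(N^2) sample entropy by direct template counting (Chebyshev, <= r,
# self-matches excluded).
oracle_sampen <- function(x, m = 2L, r) {
  n <- length(x)
  count <- function(mm) {
    nt <- n - m            # common template population for both lengths
    tot <- 0L
    for (i in 1:(nt - 1L)) {
      js <- (i + 1L):nt
      d <- abs(x[js] - x[i])
      for (off in seq_len(mm - 1L)) {
        d <- pmax(d, abs(x[js + off] - x[i + off]))
      }
      tot <- tot + sum(d <= r)
    }
    tot
  }
  B <- count(m)
  A <- count(m + 1L)
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Rosenstein local divergence rate by exhaustive neighbour search,
# mirroring the documented definition (dim, delay, Theiler window one
# stride, fit 0..k_max, distances floored at 1e-12), all in plain loops.
oracle_lde <- function(x, fs, stride_time, dim_ = 5L, delay = 10L,
                       fit_frac = 0.5) {
  n <- length(x)
  m <- n - (dim_ - 1L) * delay
  w <- round(stride_time * fs)
  k_max <- round(fit_frac * stride_time * fs)
  n_ref <- m - k_max
  E <- sapply(0:(dim_ - 1L), function(j) x[(1L + j * delay):(m + j * delay)])
  logd <- numeric(k_max + 1L)
  nn <- integer(n_ref)
  for (i in seq_len(n_ref)) {
    d2 <- rowSums((E[seq_len(n_ref), , drop = FALSE] -
                     matrix(E[i, ], n_ref, dim_, byrow = TRUE))^2)
    d2[abs(seq_len(n_ref) - i) < w] <- Inf
    nn[i] <- if (all(!is.finite(d2))) NA_integer_ else which.min(d2)
  }
  ok <- !is.na(nn)
  for (k in 0:k_max) {
    s <- 0; cnt <- 0L
    for (i in seq_len(n_ref)[ok]) {
      d <- sqrt(sum((E[i + k, ] - E[nn[i] + k, ])^2))
      s <- s + log(max(d, 1e-12)); cnt <- cnt + 1L
    }
    logd[k + 1L] <- s / cnt
  }
  kk <- 0:k_max
  slope <- sum((kk - mean(kk)) * (logd - mean(logd))) / sum((kk - mean(kk))^2)
  slope * stride_time * fs
}

# Direct O(N^2) unbiased autocovariance coefficient at one lag.
oracle_unbiased_autocorr <- function(x, lag) {
  x <- x - mean(x)
  n <- length(x)
  s <- 0
  for (t in 1:(n - lag)) s <- s + x[t] * x[t + lag]
  (s / (n - lag)) / (sum(x^2) / n)
}

# Rectangular-window periodogram power fractions (one-sided).
oracle_periodogram_fraction <- function(x, fs, f_lo, f_hi) {
  x <- x - mean(x)
  n <- length(x)
  X <- fft(x)
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2
  p[2:half] <- 2 * p[2:half]
  f <- (0:half) * fs / n
  sum(p[f >= f_lo & f <= f_hi]) / sum(p)
}

# Smallest n >= 2 with n >= f(n), by exhaustive scan.
oracle_required_n <- function(rho, r, d, alpha = 0.05, power = 0.8,
                              n_max = 1e4) {
  for (n in 2:n_max) {
    rhs <- 2 * (1 - r * rho) *
      (qt(power, n - 1) + qt(1 - alpha / 2, n - 1))^2 / d^2
    if (n >= rhs) return(n)
  }
  NA_integer_
}
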