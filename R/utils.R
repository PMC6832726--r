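# Internal helpers: scoped RNG, small-vector row medians, spectral primitives.

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Row-wise medians of a numeric matrix with few columns, fully vectorised.
# Uses a data-independent bubble compare-exchange network on whole columns,
# so cost is K^2/2 pmin/pmax passes regardless of the number of rows.
row_medians <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  k <- ncol(m)
  if (k == 1L) return(m[, 1L])
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(m[, j], m[, j + 1L])
      hi <- pmax(m[, j], m[, j + 1L])
      m[, j] <- lo
      m[, j + 1L] <- hi
    }
  }
  if (k %% 2L == 1L) m[, (k + 1L) %/% 2L] else (m[, k %/% 2L] + m[, k %/% 2L + 1L]) / 2
}

deg2rad <- function(x) x * pi / 180

# Axis order everywhere: column 1 = VT (vertical), 2 = ML, 3 = AP.
# Yaw rotates the horizontal (ML-AP) plane about VT; pitch about ML; roll about AP.
rot_yaw <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}
rot_pitch <- function(a) {
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}
rot_roll <- function(a) {
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Rotation matrix from yaw, pitch and roll angles
#'
#' Composes a rotation in the package's fixed axis order (VT, ML, AP):
#' yaw about the vertical, pitch about the mediolateral axis, roll about
#' the anteroposterior axis, applied as `R = R_yaw R_pitch R_roll`.
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return A 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(yaw = 0, pitch = 0, roll = 0) {
  rot_yaw(deg2rad(yaw)) %*% rot_pitch(deg2rad(pitch)) %*% rot_roll(deg2rad(roll))
}

# Minimal rotation mapping unit vector u onto e1 = (1,0,0) (the VT axis),
# by Rodrigues' formula about the axis u x e1.
rotation_to_vertical <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5) stop("cannot orient: zero-length mean vector")
  u <- v / nv
  e <- c(1, 0, 0)
  c_ <- sum(u * e)
  axis <- c(u[2] * e[3] - u[3] * e[2],
            u[3] * e[1] - u[1] * e[3],
            u[1] * e[2] - u[2] * e[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about ML
    return(rot_pitch(pi))
  }
  k <- axis / s
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K * s + K %*% K * (1 - c_)
}

# One-sided periodogram as power-per-bin fractions of total variance:
# sum over bins equals the mean square of the demeaned signal (Parseval).
periodogram_power <- function(x, fs, pad = 1L) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- n * max(1L, as.integer(pad))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  half <- floor(nfft / 2)
  p <- Mod(X[seq_len(half + 1L)])^2 / (n * nfft) * pad
  p[2:half] <- 2 * p[2:half]
  list(freq = (0:half) * fs / nfft, power = p)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window, 50% overlap by
#' default. Each segment is demeaned before windowing. Returns a
#' one-sided density in signal-units^2 per Hz.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in samples/s.
#' @param seg_s Segment length in seconds (default 5; capped at the
#'   signal length).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A list with `freq` (Hz), `psd`, and the bin width `df` (Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 5, overlap = 0.5) {
  n <- length(x)
  L <- min(n, max(8L, round(seg_s * fs)))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- hann_window(L)
  u <- sum(w^2)
  half <- floor(L / 2)
  acc <- numeric(half + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- Mod(X[seq_len(half + 1L)])^2 / (u * fs)
    p[2:half] <- 2 * p[2:half]
    acc <- acc + p
  }
  list(freq = (0:half) * fs / L, psd = acc / length(starts), df = fs / L)
}

# Complex Fourier coefficient of x at an arbitrary frequency f (Goertzel-style
# direct sum); `amplitude` is the matching real cosine amplitude 2|S|/N.
fourier_coefficient <- function(x, fs, f) {
  n <- length(x)
  t <- (0:(n - 1)) / fs
  sum(x * exp(-2i * pi * f * t))
}

spectral_amplitude <- function(x, fs, f) {
  2 * Mod(fourier_coefficient(x - mean(x), fs, f)) / length(x)
}
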