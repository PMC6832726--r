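# Realignment of sensor axes to anatomical VT/ML/AP.

# Step-frequency candidate from the VT channel alone (used before the full
# epoch-level detection is possible): zero-padded periodogram peak in `band`.
vt_step_frequency <- function(vt, fs, band = c(1, 4), pad = 4L) {
  pg <- periodogram_power(vt, fs, pad = pad)
  sel <- pg$freq >= band[1] & pg$freq <= band[2]
  if (!any(sel)) return(NA_real_)
  pg$freq[sel][which.max(pg$power[sel])]
}

# Power of the yaw-rotated ML channel at frequency f, as a function of the
# yaw angle psi: ml'(psi) = cos(psi) ml - sin(psi) ap.
ml_power_at <- function(a_ml, a_ap, psi) {
  Mod(cos(psi) * a_ml - sin(psi) * a_ap)^2
}

golden_section <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d)
  while (abs(b - a) > tol) {
    if (fc < fd) { b <- d; d <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d; fc <- fd; d <- a + gr * (b - a); fd <- f(d) }
  }
  (a + b) / 2
}

#' Realign an episode with the anatomical axes
#'
#' Two-stage realignment mirroring standard practice for trunk-worn
#' accelerometers: (1) the episode-mean acceleration vector (dominated by
#' gravity during upright locomotion) is rotated onto the vertical axis by
#' the minimal rotation; (2) the remaining horizontal-plane (yaw) angle is
#' chosen to minimise mediolateral power at the detected step frequency,
#' because left-right symmetric gait concentrates ML power at stride, not
#' step, frequency. Gravity (the mean vector magnitude) is then subtracted
#' from VT, leaving all three axes with zero mean.
#'
#' The yaw objective is periodic with period pi; the minimiser is located
#' by a coarse grid scan (0.5 degree) refined by golden-section search,
#' with ties broken toward the smallest absolute yaw. A flat objective
#' (no step-frequency power to steer by) yields yaw 0 with a warning.
#'
#' @param episode An [accel_episode()] of at least 2 s.
#' @param f_step_band Search band (Hz) for the step frequency.
#' @return The realigned [accel_episode()] (`aligned = TRUE`), with the
#'   applied rotation in attribute `rotation` and the yaw angle (radians)
#'   in attribute `yaw`.
#' @export
realign_axes <- function(episode, f_step_band = c(1, 4)) {
  stopifnot(inherits(episode, "accel_episode"))
  if (episode_duration(episode) < 2) stop("episode shorter than 2 s cannot be realigned")
  m <- colMeans(episode$samples)
  g_mag <- sqrt(sum(m^2))
  if (g_mag < 0.25) {
    stop("episode-mean acceleration is far from 1 g; cannot identify the gravity axis")
  }
  Q <- rotation_to_vertical(m)
  s1 <- episode$samples %*% t(Q)

  f_step <- vt_step_frequency(s1[, 1] - mean(s1[, 1]), episode$fs,
                              band = f_step_band)
  yaw <- 0
  if (is.finite(f_step)) {
    a_ml <- fourier_coefficient(s1[, 2] - mean(s1[, 2]), episode$fs, f_step)
    a_ap <- fourier_coefficient(s1[, 3] - mean(s1[, 3]), episode$fs, f_step)
    obj <- function(psi) ml_power_at(a_ml, a_ap, psi)
    grid <- seq(-pi / 2, pi / 2, by = deg2rad(0.5))
    vals <- vapply(grid, obj, numeric(1))
    spread <- max(vals) - min(vals)
    if (spread <= 1e-12 * max(max(vals), 1e-300)) {
      warning("yaw objective is flat; leaving yaw at 0")
    } else {
      i <- which.min(vals)
      lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
      yaw <- golden_section(obj, lo, hi, tol = 1e-10)
      # the objective has period pi: pick the representative nearest 0,
      # then prefer the smaller |yaw| between equivalent minimisers
      alt <- yaw - sign(yaw) * pi
      if (abs(alt) < abs(yaw) && obj(alt) <= obj(yaw) + 1e-15) yaw <- alt
    }
  } else {
    warning("no step-frequency peak found; leaving yaw at 0")
  }
  Ry <- rot_yaw(yaw)
  out <- s1 %*% t(Ry)
  out[, 1] <- out[, 1] - g_mag
  ep <- accel_episode(out, episode$fs, subject = episode$subject,
                      week = episode$week, day = episode$day, aligned = TRUE)
  attr(ep, "rotation") <- Ry %*% Q
  attr(ep, "yaw") <- yaw
  attr(ep, "gravity") <- g_mag
  ep
}

#' Split an episode into fixed-length epochs
#'
#' Consecutive non-overlapping windows of exactly `epoch_s` seconds; any
#' trailing remainder is discarded. An episode shorter than one epoch
#' yields an empty list.
#'
#' @param episode An [accel_episode()].
#' @param epoch_s Epoch length in seconds (> 0).
#' @return A list of [accel_episode()] objects, each with an `epoch`
#'   attribute giving its index within the episode.
#' @export
split_epochs <- function(episode, epoch_s = 10) {
  stopifnot(inherits(episode, "accel_episode"), epoch_s > 0)
  len <- round(epoch_s * episode$fs)
  n_ep <- floor(nrow(episode$samples) / len)
  if (n_ep < 1L) return(list())
  lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    ep <- accel_episode(episode$samples[idx, , drop = FALSE], episode$fs,
                        subject = episode$subject, week = episode$week,
                        day = episode$day, aligned = episode$aligned)
    attr(ep, "epoch") <- i
    ep
  })
}

#' Detect step and stride frequency of an epoch
#'
#' The step frequency is the location of maximum combined VT+AP power in
#' the search band (zero-padded periodogram). The stride frequency is
#' found from the unbiased autocorrelation of the VT channel: the highest
#' positive peak at lags within +/-25% of two step periods, refined by
#' parabolic interpolation.
#'
#' @param epoch A realigned [accel_episode()].
#' @param band Step-frequency search band in Hz (default `c(1, 4)`).
#' @param stride_band_frac Half-width of the stride-lag search band as a
#'   fraction of the nominal stride time `2 / f_step`.
#' @param min_peak Minimum unbiased autocorrelation at the stride lag for
#'   the epoch to count as gait. A bare positive-peak criterion would
#'   accept about half of all white-noise epochs by chance; gait epochs
#'   sit well above 0.2.
#' @return A list with `f_step` (Hz), `f_stride` (strides/s),
#'   `stride_time` (s), and `valid` (FALSE when no autocorrelation peak
#'   reaches `min_peak` in the band, e.g. for non-gait signals).
#' @export
detect_frequencies <- function(epoch, band = c(1, 4), stride_band_frac = 0.25,
                               min_peak = 0.2) {
  stopifnot(inherits(epoch, "accel_episode"))
  fs <- epoch$fs
  vt <- epoch$samples[, 1] - mean(epoch$samples[, 1])
  ap <- epoch$samples[, 3] - mean(epoch$samples[, 3])
  pg_vt <- periodogram_power(vt, fs, pad = 4L)
  pg_ap <- periodogram_power(ap, fs, pad = 4L)
  pow <- pg_vt$power + pg_ap$power
  sel <- pg_vt$freq >= band[1] & pg_vt$freq <= band[2]
  invalid <- list(f_step = NA_real_, f_stride = NA_real_,
                  stride_time = NA_real_, valid = FALSE)
  if (!any(sel) || all(pow[sel] <= 0)) return(invalid)
  f_step <- pg_vt$freq[sel][which.max(pow[sel])]

  stride_lag0 <- 2 / f_step * fs
  lags <- seq(max(1L, round(stride_lag0 * (1 - stride_band_frac))),
              round(stride_lag0 * (1 + stride_band_frac)))
  n <- length(vt)
  lags <- lags[lags < n - 1L]
  if (!length(lags)) return(invalid)
  ac <- unbiased_autocorr(vt, lags)
  if (!any(ac > min_peak)) return(invalid)
  i <- which.max(ac)
  lag_hat <- lags[i]
  # parabolic refinement needs both neighbours of the winning lag
  acm <- unbiased_autocorr(vt, c(lag_hat - 1L, lag_hat, lag_hat + 1L))
  denom <- acm[1] - 2 * acm[2] + acm[3]
  delta <- if (abs(denom) > 1e-15) 0.5 * (acm[1] - acm[3]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  lag_ref <- lag_hat + delta
  f_stride <- fs / lag_ref
  list(f_step = f_step, f_stride = f_stride, stride_time = 1 / f_stride,
       valid = TRUE)
}

# Unbiased (lag-corrected) autocorrelation coefficient at integer lags.
unbiased_autocorr <- function(x, lags) {
  x <- x - mean(x)
  n <- length(x)
  v <- sum(x^2) / n
  vapply(lags, function(k) {
    if (k >= n) return(NA_real_)
    sum(x[1:(n - k)] * x[(k + 1):n]) / (n - k) / v
  }, numeric(1))
}
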