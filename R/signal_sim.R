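# Synthetic gait-like tri-axial trunk acceleration with known ground truth.

#' Parameters for the synthetic gait signal generator
#'
#' Describes a gait-like tri-axial acceleration episode. Vertical (VT) and
#' anteroposterior (AP) power is placed at multiples of the step frequency
#' (twice the stride frequency), mediolateral (ML) power at multiples of the
#' stride frequency, mirroring the spectral signature of symmetric bipedal
#' gait. A per-stride random-walk phase perturbation makes regularity,
#' sample entropy and local divergence rate tunable with a single knob.
#'
#' @param duration_s Episode duration in seconds.
#' @param fs Sampling rate in samples/s (sensor default 100).
#' @param f_stride Stride frequency in strides/s; step frequency is
#'   `2 * f_stride`.
#' @param vt_harmonics,ap_harmonics Cosine amplitudes (g) at multiples
#'   1, 2, ... of the step frequency.
#' @param ml_harmonics Cosine amplitudes (g) at multiples of the stride
#'   frequency.
#' @param asymmetry Fraction in `[0, 1]` of ML fundamental power leaked to
#'   the step frequency (asymmetric gait concentrates ML power at step
#'   rather than stride frequency).
#' @param phase_jitter_sd Standard deviation (radians) of the per-stride
#'   random-walk increment of the common gait phase. 0 gives a perfectly
#'   periodic signal.
#' @param noise_sd Additive white-noise standard deviation in g.
#' @param gravity_g Constant acceleration added to the VT axis (default 1 g).
#' @param yaw,pitch,roll Sensor misalignment angles in degrees, applied as
#'   the final rotation (so the stored axes are "sensor" axes until
#'   [realign_axes()] is applied).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `gait_signal_params`.
#' @seealso [simulate_gait_episode()]
#' @export
gait_signal_params <- function(duration_s = 60, fs = 100, f_stride = 0.9,
                               vt_harmonics = c(0.30, 0.10, 0.05),
                               ml_harmonics = c(0.20, 0.07),
                               ap_harmonics = c(0.25, 0.08, 0.04),
                               asymmetry = 0, phase_jitter_sd = 0,
                               noise_sd = 0, gravity_g = 1,
                               yaw = 0, pitch = 0, roll = 0, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, f_stride > 0,
            all(vt_harmonics >= 0), all(ml_harmonics >= 0),
            all(ap_harmonics >= 0),
            asymmetry >= 0, asymmetry <= 1,
            phase_jitter_sd >= 0, noise_sd >= 0)
  f_step <- 2 * f_stride
  f_max <- max(length(vt_harmonics) * f_step,
               length(ap_harmonics) * f_step,
               length(ml_harmonics) * f_stride,
               f_step)
  if (fs <= 2 * f_max) {
    stop(sprintf(paste("sampling rate %g does not satisfy the Nyquist",
                       "condition for the highest generated harmonic (%g Hz);",
                       "increase fs or drop harmonics"), fs, f_max))
  }
  structure(list(duration_s = duration_s, fs = fs, f_stride = f_stride,
                 vt_harmonics = vt_harmonics, ml_harmonics = ml_harmonics,
                 ap_harmonics = ap_harmonics, asymmetry = asymmetry,
                 phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd,
                 gravity_g = gravity_g, yaw = yaw, pitch = pitch,
                 roll = roll, seed = as.integer(seed)),
            class = "gait_signal_params")
}

#' Construct a tri-axial acceleration episode
#'
#' @param samples N x 3 numeric matrix of accelerations in g; columns are
#'   VT, ML, AP once realigned (arbitrary sensor axes before realignment).
#' @param fs Sampling rate in samples/s.
#' @param subject,week,day Integer labels; `week` is 1 or 2.
#' @param aligned Logical: have the axes been realigned to anatomical
#'   VT/ML/AP with gravity removed?
#' @return An object of class `accel_episode`.
#' @export
accel_episode <- function(samples, fs, subject = 1L, week = 1L, day = 1L,
                          aligned = FALSE) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 3, nrow(samples) >= 2, is.numeric(samples),
            all(is.finite(samples)), fs > 0, week %in% c(1L, 2L))
  if (any(abs(samples) > 6 + 1e-9)) {
    stop("acceleration outside the +/-6 g sensor range")
  }
  dimnames(samples) <- list(NULL, c("vt", "ml", "ap"))
  structure(list(samples = samples, fs = fs,
                 subject = as.integer(subject), week = as.integer(week),
                 day = as.integer(day), aligned = isTRUE(aligned)),
            class = "accel_episode")
}

#' @export
print.accel_episode <- function(x, ...) {
  cat(sprintf("<accel_episode> subject %d week %d day %d: %.1f s @ %g Hz (%s)\n",
              x$subject, x$week, x$day, nrow(x$samples) / x$fs, x$fs,
              if (x$aligned) "aligned VT/ML/AP" else "raw sensor axes"))
  invisible(x)
}

episode_duration <- function(episode) nrow(episode$samples) / episode$fs

#' Simulate one gait-like acceleration episode
#'
#' Builds VT and AP channels as cosine sums at multiples of the step
#' frequency and the ML channel at multiples of the stride frequency, all
#' driven by a common stride phase that accumulates a Gaussian random-walk
#' perturbation once per stride (linearly interpolated within strides).
#' Gravity is added to VT, the misalignment rotation is applied last,
#' white noise is added, and samples are clipped to the +/-6 g sensor
#' range (the clipped-sample count is attached as attribute `n_clipped`
#' and reported via a message when non-zero).
#'
#' @param params A [gait_signal_params()] object.
#' @param subject,week,day Labels carried into the episode.
#' @return An [accel_episode()], not yet realigned.
#' @export
simulate_gait_episode <- function(params, subject = 1L, week = 1L, day = 1L) {
  stopifnot(inherits(params, "gait_signal_params"))
  p <- params
  n <- round(p$duration_s * p$fs)
  t <- (0:(n - 1)) / p$fs
  seed_val <- (as.numeric(p$seed) + 7919 * (as.numeric(subject) %% 1000) +
                 104729 * as.numeric(week) + 1299709 * as.numeric(day)) %% 2147483647
  with_seed(seed_val, {
    n_strides <- ceiling(p$duration_s * p$f_stride) + 1L
    theta <- if (p$phase_jitter_sd > 0) {
      cumsum(c(0, stats::rnorm(n_strides, 0, p$phase_jitter_sd)))
    } else {
      rep(0, n_strides + 1L)
    }
    # common stride phase, 2*pi per stride, jitter interpolated within strides
    stride_pos <- t * p$f_stride
    idx <- floor(stride_pos)
    frac <- stride_pos - idx
    jit <- theta[idx + 1L] * (1 - frac) + theta[idx + 2L] * frac
    phi <- 2 * pi * stride_pos + jit          # stride phase
    vt <- rep(0, n); ap <- rep(0, n); ml <- rep(0, n)
    for (k in seq_along(p$vt_harmonics)) {
      vt <- vt + p$vt_harmonics[k] * cos(2 * k * phi)
    }
    for (k in seq_along(p$ap_harmonics)) {
      ap <- ap + p$ap_harmonics[k] * cos(2 * k * phi + pi / 2)
    }
    if (length(p$ml_harmonics)) {
      a1 <- p$ml_harmonics[1]
      ml <- ml + a1 * sqrt(1 - p$asymmetry) * cos(phi) +
        a1 * sqrt(p$asymmetry) * cos(2 * phi + pi / 3)
      for (k in seq_along(p$ml_harmonics)[-1]) {
        ml <- ml + p$ml_harmonics[k] * cos(k * phi)
      }
    }
    vt <- vt + p$gravity_g
    m <- cbind(vt, ml, ap)
    R <- rotation_matrix(p$yaw, p$pitch, p$roll)
    m <- m %*% t(R)
    if (p$noise_sd > 0) m <- m + stats::rnorm(3L * n, 0, p$noise_sd)
    n_clipped <- sum(abs(m) > 6)
    if (n_clipped > 0) {
      m <- pmin(pmax(m, -6), 6)
      message(sprintf("simulate_gait_episode: clipped %d samples at +/-6 g",
                      n_clipped))
    }
    ep <- accel_episode(m, p$fs, subject = subject, week = week, day = day,
                        aligned = FALSE)
    attr(ep, "n_clipped") <- n_clipped
    ep
  })
}

#' Write episodes to a delimiter-separated text file
#'
#' One row per sample with header
#' `subject,week,day,t,acc_vt,acc_ml,acc_ap`; time in seconds,
#' acceleration in g. Axis columns carry sensor axes for raw episodes and
#' anatomical axes for realigned ones.
#'
#' @param episodes A single [accel_episode()] or a list of them.
#' @param path Output file path.
#' @export
write_episodes <- function(episodes, path) {
  if (inherits(episodes, "accel_episode")) episodes <- list(episodes)
  rows <- lapply(episodes, function(ep) {
    n <- nrow(ep$samples)
    data.frame(subject = ep$subject, week = ep$week, day = ep$day,
               t = (0:(n - 1)) / ep$fs,
               acc_vt = ep$samples[, 1], acc_ml = ep$samples[, 2],
               acc_ap = ep$samples[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read episodes from a delimiter-separated text file
#'
#' Inverse of [write_episodes()]. The sampling rate is inferred from the
#' median time step of each episode. Column names for the axes can be
#' remapped via `axis_cols` for files from other sources.
#'
#' @param path Input file path.
#' @param axis_cols Character vector of length 3 naming the VT, ML, AP
#'   columns in the file.
#' @return A list of [accel_episode()] objects, one per distinct
#'   (subject, week, day).
#' @export
read_episodes <- function(path, axis_cols = c("acc_vt", "acc_ml", "acc_ap")) {
  df <- utils::read.csv(path)
  need <- c("subject", "week", "day", "t", axis_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("episode file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(df$subject, df$week, df$day, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t), ]
    fs <- 1 / stats::median(diff(d$t))
    accel_episode(as.matrix(d[, axis_cols]), fs = round(fs, 6),
                  subject = d$subject[1], week = d$week[1], day = d$day[1])
  })
}
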