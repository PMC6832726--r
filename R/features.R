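# Gait-quality characteristics computed on realigned 10-s epochs.

#' Feature-extraction configuration
#'
#' Central collection of the tunable parameters of the extraction chain.
#' Defaults follow common practice for trunk accelerometry in older
#' adults; every value can be overridden.
#'
#' @param epoch_s Epoch length in seconds.
#' @param f_step_band Step-frequency search band in Hz.
#' @param stride_band_frac Stride-lag search half-width (fraction of the
#'   nominal stride time).
#' @param units `"ms2"` (default) converts accelerations to m/s^2 for the
#'   dispersion features; `"g"` keeps sensor units.
#' @param leg_length Default leg length in metres, used (with a warning)
#'   when a call does not supply one.
#' @param welch_seg_s Welch segment length in seconds.
#' @param ih_halfwidth Half-width (Hz) of the integration window around
#'   each harmonic for the index of harmonicity.
#' @param hr_n_harmonics Number of stride harmonics for the harmonic ratio.
#' @param hr_cap Cap applied to the harmonic ratio when the denominator
#'   vanishes.
#' @param lde_dim,lde_delay Delay-embedding dimension and delay (samples)
#'   for the local divergence rate.
#' @param lde_fit_frac Fraction of a stride over which the divergence
#'   slope is fitted.
#' @param lde_min_points Minimum number of embedded points.
#' @param sampen_m,sampen_r_frac Sample-entropy template length and
#'   tolerance as a fraction of the signal SD.
#' @param min_epochs Minimum valid epochs per subject-week for the weekly
#'   median (used by [weekly_median_table()]).
#' @param composite Optional [composite_weights()] used by
#'   [extract_features()].
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(epoch_s = 10, f_step_band = c(1, 4),
                           stride_band_frac = 0.25, units = c("ms2", "g"),
                           leg_length = 0.9, welch_seg_s = 5,
                           ih_halfwidth = 0.1, hr_n_harmonics = 20,
                           hr_cap = 100, lde_dim = 5, lde_delay = 10,
                           lde_fit_frac = 0.5, lde_min_points = 100,
                           sampen_m = 2, sampen_r_frac = 0.2,
                           min_epochs = 10, composite = NULL) {
  units <- match.arg(units)
  stopifnot(epoch_s > 0, leg_length > 0, hr_n_harmonics >= 2,
            lde_dim >= 2, lde_delay >= 1, sampen_m >= 1)
  structure(as.list(environment()), class = "feature_config")
}

G_TO_MS2 <- 9.80665

axis_scale <- function(config) if (config$units == "ms2") G_TO_MS2 else 1

#' Per-axis dispersion of a realigned epoch
#'
#' Standard deviation and range (max - min) per axis, on gravity-removed
#' signals, in the units selected by the configuration (m/s^2 by default).
#'
#' @param epoch A realigned [accel_episode()].
#' @param config A [feature_config()].
#' @return Named list: `sd_vt`, `sd_ml`, `sd_ap`, `range_vt`, `range_ml`,
#'   `range_ap`.
#' @export
dispersion_features <- function(epoch, config = feature_config()) {
  s <- epoch$samples * axis_scale(config)
  sds <- apply(s, 2, stats::sd)
  rngs <- apply(s, 2, function(x) diff(range(x)))
  list(sd_vt = sds[1], sd_ml = sds[2], sd_ap = sds[3],
       range_vt = rngs[1], range_ml = rngs[2], range_ap = rngs[3])
}

#' Stride regularity (unbiased autocorrelation at one stride)
#'
#' Lag-corrected autocorrelation coefficient of each axis at the stride
#' lag; the local maximum within +/-10% of `round(stride_time * fs)` is
#' taken and the result clamped to `[-1, 1]`.
#'
#' @param epoch A realigned [accel_episode()].
#' @param stride_time Stride time in seconds.
#' @return Named list `stride_autocorr_vt`, `stride_autocorr_ml`,
#'   `stride_autocorr_ap`, or `NULL` when the stride lag exceeds half the
#'   epoch (too few strides to compare).
#' @export
stride_regularity <- function(epoch, stride_time) {
  fs <- epoch$fs
  n <- nrow(epoch$samples)
  lag0 <- round(stride_time * fs)
  if (lag0 >= n / 2) return(NULL)
  lags <- seq(max(1L, round(0.9 * lag0)), min(n - 2L, round(1.1 * lag0)))
  vals <- apply(epoch$samples, 2, function(x) {
    ac <- unbiased_autocorr(x, lags)
    max(-1, min(1, max(ac)))
  })
  list(stride_autocorr_vt = vals[1], stride_autocorr_ml = vals[2],
       stride_autocorr_ap = vals[3])
}

#' Dominant spectral peak amplitude and width
#'
#' From a Welch spectrum normalised to unit total power: the dominant
#' amplitude is the power fraction in the dominant peak bin plus the
#' adjacent contiguous main-lobe bins (power above a tenth of the peak,
#' which is below the Hann side-bin level of a pure tone but above the
#' broadband floor); the width is the frequency span of the half-power
#' region in Hz. A flat spectrum yields the full band as width, with a
#' warning.
#'
#' @param epoch A realigned [accel_episode()].
#' @param config A [feature_config()].
#' @return Named list with `dominant_amp_vt/ml/ap` (power fractions) and
#'   `dominant_width_vt/ml/ap` (Hz).
#' @export
spectral_peak_features <- function(epoch, config = feature_config()) {
  one_axis <- function(x) {
    w <- welch_psd(x, epoch$fs, seg_s = config$welch_seg_s)
    tot <- sum(w$psd)
    if (!is.finite(tot) || tot <= 0) {
      warning("flat spectrum: dominant-peak width set to the full band")
      return(c(amp = NA_real_, width = max(w$freq) - min(w$freq)))
    }
    p <- w$psd / tot
    i <- which.max(p)
    half <- p[i] / 2
    # peak membership threshold must sit below the Hann main-lobe side
    # bins (exactly peak/4 for an on-bin tone) and above the broadband
    # floor, otherwise side-bin inclusion flips with the noise draw
    lobe <- p[i] / 10
    if (min(p) >= half) {
      warning("flat spectrum: dominant-peak width set to the full band")
      return(c(amp = sum(p), width = max(w$freq) - min(w$freq)))
    }
    lo <- i
    while (lo > 1L && p[lo - 1L] >= lobe) lo <- lo - 1L
    hi <- i
    while (hi < length(p) && p[hi + 1L] >= lobe) hi <- hi + 1L
    amp <- sum(p[lo:hi])
    in_half <- p[lo:hi] >= half
    c(amp = amp, width = sum(in_half) * w$df)
  }
  v <- one_axis(epoch$samples[, 1])
  m <- one_axis(epoch$samples[, 2])
  a <- one_axis(epoch$samples[, 3])
  list(dominant_amp_vt = v["amp"], dominant_amp_ml = m["amp"],
       dominant_amp_ap = a["amp"],
       dominant_width_vt = v["width"], dominant_width_ml = m["width"],
       dominant_width_ap = a["width"])
}

#' Index of harmonicity
#'
#' Ratio of the spectral power at the fundamental gait frequency to the
#' summed power of the first six harmonics, each integrated over a narrow
#' window around the harmonic. The fundamental is the step frequency for
#' VT and AP and the stride frequency for ML. Values lie in `[0, 1]`;
#' 1 means perfectly harmonic.
#'
#' @param epoch A realigned [accel_episode()].
#' @param freqs Output of [detect_frequencies()].
#' @param config A [feature_config()].
#' @return Named list `ih_vt`, `ih_ml`, `ih_ap` (NA with zero harmonic
#'   power).
#' @export
index_of_harmonicity <- function(epoch, freqs, config = feature_config()) {
  hw <- config$ih_halfwidth
  one_axis <- function(x, f0) {
    pg <- periodogram_power(x, epoch$fs)
    pk <- vapply(1:6, function(k) {
      sel <- pg$freq >= k * f0 - hw & pg$freq <= k * f0 + hw
      sum(pg$power[sel])
    }, numeric(1))
    tot <- sum(pk)
    if (tot <= 0) return(NA_real_)
    pk[1] / tot
  }
  list(ih_vt = one_axis(epoch$samples[, 1], freqs$f_step),
       ih_ml = one_axis(epoch$samples[, 2], freqs$f_stride),
       ih_ap = one_axis(epoch$samples[, 3], freqs$f_step))
}

#' Harmonic ratio
#'
#' Spectral amplitudes at the first `hr_n_harmonics` multiples of the
#' stride frequency; for VT and AP the ratio of summed even-harmonic to
#' summed odd-harmonic amplitudes (higher = more bilaterally symmetric),
#' inverted (odd/even) for ML. When the denominator falls below machine
#' precision the ratio is capped at `hr_cap` with a warning.
#'
#' @param epoch A realigned [accel_episode()].
#' @param freqs Output of [detect_frequencies()].
#' @param config A [feature_config()].
#' @return Named list `hr_vt`, `hr_ml`, `hr_ap`.
#' @export
harmonic_ratio <- function(epoch, freqs, config = feature_config()) {
  kmax <- config$hr_n_harmonics
  one_axis <- function(x, invert) {
    amps <- vapply(seq_len(kmax), function(k)
      spectral_amplitude(x, epoch$fs, k * freqs$f_stride), numeric(1))
    even <- sum(amps[seq(2, kmax, by = 2)])
    odd <- sum(amps[seq(1, kmax, by = 2)])
    num <- if (invert) odd else even
    den <- if (invert) even else odd
    if (den < .Machine$double.eps * max(1, num)) {
      warning("harmonic-ratio denominator is at machine precision; capping")
      return(config$hr_cap)
    }
    min(num / den, config$hr_cap)
  }
  list(hr_vt = one_axis(epoch$samples[, 1], FALSE),
       hr_ml = one_axis(epoch$samples[, 2], TRUE),
       hr_ap = one_axis(epoch$samples[, 3], FALSE))
}

# Frequency-domain double integration of acceleration to displacement in a
# band: X_pos(f) = -X_acc(f) / (2 pi f)^2 inside [f_lo, f_hi], 0 outside.
integrate_twice_fft <- function(acc, fs, f_lo, f_hi) {
  n <- length(acc)
  X <- stats::fft(acc - mean(acc))
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) * fs / n
  H <- ifelse(abs(f) >= f_lo & abs(f) <= f_hi & f != 0,
              -1 / (2 * pi * f)^2, 0)
  Re(stats::fft(X * H, inverse = TRUE)) / n
}

#' Walking speed and stride length from vertical acceleration
#'
#' Inverted-pendulum estimate: the VT acceleration (converted to m/s^2)
#' is band-passed and doubly integrated in the frequency domain to a
#' vertical displacement; `h` is the mean peak-to-peak vertical excursion
#' per step; step length follows the inverted-pendulum chord
#' `2 * sqrt(2 * leg_length * h - h^2)`; walking speed is step length
#' times step frequency; stride length is twice the step length.
#'
#' @param epoch A realigned [accel_episode()].
#' @param freqs Output of [detect_frequencies()].
#' @param leg_length Leg length in metres; when `NULL` the configured
#'   default is used with a warning.
#' @param config A [feature_config()].
#' @return Named list `walking_speed` (m/s), `stride_length` (m), `h` (m).
#' @export
walking_speed_and_stride_length <- function(epoch, freqs, leg_length = NULL,
                                            config = feature_config()) {
  if (is.null(leg_length)) {
    warning(sprintf("leg length not supplied; using configured default %.2f m",
                    config$leg_length))
    leg_length <- config$leg_length
  }
  stopifnot(leg_length > 0, isTRUE(freqs$valid))
  fs <- epoch$fs
  acc <- epoch$samples[, 1] * G_TO_MS2
  pos <- integrate_twice_fft(acc, fs, 0.1, 3 * freqs$f_step)
  step_len_samples <- 1 / freqs$f_step * fs
  n_steps <- floor(length(pos) / step_len_samples)
  if (n_steps < 2) stop("epoch too short for per-step excursion estimation")
  h_per_step <- vapply(seq_len(n_steps), function(i) {
    idx <- (round((i - 1) * step_len_samples) + 1):round(i * step_len_samples)
    diff(range(pos[idx]))
  }, numeric(1))
  h <- mean(h_per_step)
  if (h >= leg_length) {
    stop(sprintf("vertical excursion %.3f m >= leg length %.3f m (non-physical)",
                 h, leg_length))
  }
  step_length <- 2 * sqrt(2 * leg_length * h - h^2)
  speed <- step_length * freqs$f_step
  list(walking_speed = speed, stride_length = 2 * step_length, h = h)
}

#' Local divergence rate (short-term, per stride)
#'
#' Rosenstein-style maximum divergence exponent of a single-axis signal:
#' delay embedding, nearest neighbour per point excluding temporally
#' close pairs (within one stride), mean log Euclidean divergence curve,
#' least-squares slope over 0 to `lde_fit_frac` strides, rescaled to
#' log-units per stride. Distances are floored at 1e-12 so exactly
#' periodic signals yield a flat (zero-slope) divergence curve instead of
#' log-of-zero noise.
#'
#' @param epoch A realigned [accel_episode()] (>= 10 s recommended).
#' @param stride_time Stride time in seconds.
#' @param config A [feature_config()].
#' @param axes Which axes to compute (default VT and AP, the two the
#'   falls literature uses).
#' @return Named list `lde_vt`, `lde_ap` (and `lde_ml` if requested);
#'   `NULL` when fewer than `lde_min_points` embedded points remain.
#' @export
local_divergence_rate <- function(epoch, stride_time,
                                  config = feature_config(),
                                  axes = c("vt", "ap")) {
  fs <- epoch$fs
  dim_ <- config$lde_dim
  delay <- config$lde_delay
  w_theiler <- round(stride_time * fs)
  k_max <- round(config$lde_fit_frac * stride_time * fs)
  one_axis <- function(x) {
    n <- length(x)
    m <- n - (dim_ - 1L) * delay
    if (m < config$lde_min_points) return(NULL)
    Y <- sapply(0:(dim_ - 1L), function(j) x[(1 + j * delay):(m + j * delay)])
    n_ref <- m - k_max
    if (n_ref < 2L) return(NULL)
    D <- as.matrix(stats::dist(Y))
    idx <- seq_len(n_ref)
    ii <- abs(outer(idx, idx, "-")) < w_theiler
    Dn <- D[idx, idx]
    Dn[ii] <- Inf
    nn <- apply(Dn, 1L, which.min)
    ok <- is.finite(Dn[cbind(idx, nn)])
    if (sum(ok) < 2L) return(NULL)
    ref <- idx[ok]; nbr <- nn[ok]
    logd <- vapply(0:k_max, function(k)
      mean(log(pmax(D[cbind(ref + k, nbr + k)], 1e-12))), numeric(1))
    kk <- 0:k_max
    slope <- stats::cov(kk, logd) / stats::var(kk)
    slope * stride_time * fs          # per stride
  }
  cols <- c(vt = 1L, ml = 2L, ap = 3L)[axes]
  out <- lapply(cols, function(j) one_axis(epoch$samples[, j]))
  if (any(vapply(out, is.null, logical(1)))) return(NULL)
  stats::setNames(out, paste0("lde_", names(cols)))
}

#' Sample entropy
#'
#' `SampEn(m, r)` with template length `m` (default 2) and tolerance
#' `r = sampen_r_frac * SD` of the axis signal (default 0.2 SD),
#' Chebyshev distance, self-matches excluded: `-ln(A/B)` where `B` and
#' `A` count template pairs matching at lengths `m` and `m + 1`.
#'
#' @param epoch A realigned [accel_episode()] (>= 200 samples).
#' @param config A [feature_config()].
#' @param axes Axes to compute (default ML, the axis the falls
#'   literature uses).
#' @param r Optional explicit tolerance overriding the SD-based default.
#' @return Named list (e.g. `sampen_ml`); entries are `NA` when `A` or
#'   `B` is zero (no matches to condition on).
#' @export
sample_entropy <- function(epoch, config = feature_config(), axes = "ml",
                           r = NULL) {
  m <- config$sampen_m
  one_axis <- function(x) {
    n <- length(x)
    if (n < 200L) return(NA_real_)
    rr <- if (is.null(r)) config$sampen_r_frac * stats::sd(x) else r
    # count over the common n - m template range so A/B is a conditional
    # probability on the same pair population
    nm <- n - m
    Em <- sapply(0:(m - 1L), function(j) x[(1 + j):(nm + j)])
    Em1 <- sapply(0:m, function(j) x[(1 + j):(nm + j)])
    B <- sum(stats::dist(Em, method = "maximum") <= rr)
    A <- sum(stats::dist(Em1, method = "maximum") <= rr)
    if (A == 0 || B == 0) return(NA_real_)
    -log(A / B)
  }
  cols <- c(vt = 1L, ml = 2L, ap = 3L)[axes]
  out <- lapply(cols, function(j) one_axis(epoch$samples[, j]))
  stats::setNames(out, paste0("sampen_", names(cols)))
}

#' Composite gait-quality score weights
#'
#' The composite score is a weighted sum of standardized inputs:
#' stride-frequency autocorrelation, power at step frequency, root mean
#' square of the accelerations, and index of harmonicity. Exact weights
#' from the original composite are external; by default all weights are
#' 1 and standardization means/SDs must be supplied (typically cohort
#' estimates).
#'
#' @param weights Named numeric vector over
#'   `c("regularity", "step_power", "rms", "harmonicity")`.
#' @param means,sds Standardization constants in the same order; `sds`
#'   must be positive.
#' @param inputs Mapping from composite input to feature column.
#' @return An object of class `composite_weights`.
#' @export
composite_weights <- function(weights = c(regularity = 1, step_power = 1,
                                          rms = 1, harmonicity = 1),
                              means = c(regularity = 0, step_power = 0,
                                        rms = 0, harmonicity = 0),
                              sds = c(regularity = 1, step_power = 1,
                                      rms = 1, harmonicity = 1),
                              inputs = c(regularity = "stride_autocorr_vt",
                                         step_power = "dominant_amp_vt",
                                         rms = "rms",
                                         harmonicity = "ih_vt")) {
  nm <- c("regularity", "step_power", "rms", "harmonicity")
  stopifnot(setequal(names(weights), nm), setequal(names(means), nm),
            setequal(names(sds), nm), all(is.finite(weights)),
            all(is.finite(means)), all(sds > 0))
  structure(list(weights = weights[nm], means = means[nm], sds = sds[nm],
                 inputs = inputs[nm]), class = "composite_weights")
}

#' Composite gait-quality score
#'
#' Each input is standardized by the configured mean/SD, multiplied by
#' its weight, and summed; linear in every input. Any missing input
#' propagates to a missing composite.
#'
#' @param features A named list or one-row data frame carrying the
#'   feature columns named in `weights$inputs` (an `rms` column is
#'   derived from `sd_vt/ml/ap` when absent).
#' @param weights A [composite_weights()] object.
#' @return Scalar composite score (NA if any input is missing).
#' @export
composite_score <- function(features, weights = composite_weights()) {
  stopifnot(inherits(weights, "composite_weights"))
  f <- as.list(features)
  if (is.null(f$rms) && !is.null(f$sd_vt)) {
    f$rms <- sqrt(f$sd_vt^2 + f$sd_ml^2 + f$sd_ap^2)
  }
  vals <- vapply(weights$inputs, function(col) {
    v <- f[[col]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (any(!is.finite(vals))) return(NA_real_)
  sum(weights$weights * (vals - weights$means) / weights$sds)
}

#' Extract the full characteristic set from one episode
#'
#' Realigns the episode (unless already aligned), splits it into
#' fixed-length epochs, and computes the characteristic set per epoch.
#' Epochs without a detectable gait rhythm are flagged invalid and kept
#' (never silently dropped); per-epoch errors are collected into the
#' `report` attribute rather than aborting the batch.
#'
#' @param episode An [accel_episode()].
#' @param config A [feature_config()].
#' @param leg_length Leg length in metres (NULL uses the configured
#'   default, with one warning per episode).
#' @return A data frame, one row per epoch, with subject/week/day/epoch
#'   labels, a `valid` flag, and one column per characteristic. The
#'   attribute `report` lists epoch-level failures.
#' @export
extract_features <- function(episode, config = feature_config(),
                             leg_length = NULL) {
  stopifnot(inherits(episode, "accel_episode"))
  if (!episode$aligned) episode <- realign_axes(episode, config$f_step_band)
  if (is.null(leg_length)) {
    warning(sprintf("leg length not supplied; using configured default %.2f m",
                    config$leg_length))
    leg_length <- config$leg_length
  }
  epochs <- split_epochs(episode, config$epoch_s)
  report <- character(0)
  na_row <- function(i) {
    data.frame(subject = episode$subject, week = episode$week,
               day = episode$day, epoch = i, valid = FALSE,
               walking_speed = NA_real_, stride_frequency = NA_real_,
               stride_length = NA_real_,
               sd_vt = NA_real_, sd_ml = NA_real_, sd_ap = NA_real_,
               range_ap = NA_real_, rms = NA_real_,
               stride_autocorr_vt = NA_real_, stride_autocorr_ap = NA_real_,
               dominant_amp_vt = NA_real_, dominant_amp_ml = NA_real_,
               dominant_amp_ap = NA_real_, dominant_width_ap = NA_real_,
               ih_vt = NA_real_, ih_ml = NA_real_, hr_vt = NA_real_,
               lde_vt = NA_real_, lde_ap = NA_real_, sampen_ml = NA_real_,
               composite = NA_real_)
  }
  rows <- lapply(seq_along(epochs), function(i) {
    ep <- epochs[[i]]
    out <- tryCatch({
      freqs <- detect_frequencies(ep, config$f_step_band,
                                  config$stride_band_frac)
      if (!freqs$valid) {
        report <<- c(report, sprintf("epoch %d: no gait rhythm detected", i))
        return(na_row(i))
      }
      disp <- dispersion_features(ep, config)
      reg <- stride_regularity(ep, freqs$stride_time)
      spec <- spectral_peak_features(ep, config)
      ih <- index_of_harmonicity(ep, freqs, config)
      hr <- harmonic_ratio(ep, freqs, config)
      lde <- local_divergence_rate(ep, freqs$stride_time, config)
      se <- sample_entropy(ep, config)
      spd <- walking_speed_and_stride_length(ep, freqs, leg_length, config)
      if (is.null(reg) || is.null(lde)) {
        report <<- c(report, sprintf("epoch %d: too short for stride-lag features", i))
        return(na_row(i))
      }
      row <- na_row(i)
      row$valid <- TRUE
      row$walking_speed <- spd$walking_speed
      row$stride_frequency <- freqs$f_stride
      row$stride_length <- spd$stride_length
      row$sd_vt <- disp$sd_vt; row$sd_ml <- disp$sd_ml; row$sd_ap <- disp$sd_ap
      row$range_ap <- disp$range_ap
      row$rms <- sqrt(disp$sd_vt^2 + disp$sd_ml^2 + disp$sd_ap^2)
      row$stride_autocorr_vt <- reg$stride_autocorr_vt
      row$stride_autocorr_ap <- reg$stride_autocorr_ap
      row$dominant_amp_vt <- spec$dominant_amp_vt
      row$dominant_amp_ml <- spec$dominant_amp_ml
      row$dominant_amp_ap <- spec$dominant_amp_ap
      row$dominant_width_ap <- spec$dominant_width_ap
      row$ih_vt <- ih$ih_vt; row$ih_ml <- ih$ih_ml
      row$hr_vt <- hr$hr_vt
      row$lde_vt <- lde$lde_vt; row$lde_ap <- lde$lde_ap
      row$sampen_ml <- se$sampen_ml
      if (!is.null(config$composite)) {
        row$composite <- composite_score(row, config$composite)
      }
      row
    }, error = function(e) {
      report <<- c(report, sprintf("epoch %d: %s", i, conditionMessage(e)))
      na_row(i)
    })
    out
  })
  out <- if (length(rows)) do.call(rbind, rows) else na_row(1L)[0, ]
  attr(out, "report") <- report
  out
}
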