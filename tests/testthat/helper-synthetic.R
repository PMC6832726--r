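# Fixture builders shared across test files.

# A clean, already-aligned gait episode (gravity removed) built directly
# as an accel_episode; duration an integer number of strides by default.
aligned_episode <- function(duration_s = 10, fs = 100, f_stride = 1,
                            jitter = 0, noise = 0, seed = 1) {
  p <- gait_signal_params(duration_s = duration_s, fs = fs,
                          f_stride = f_stride, phase_jitter_sd = jitter,
                          noise_sd = noise, seed = seed)
  ep <- simulate_gait_episode(p)
  s <- ep$samples
  s[, 1] <- s[, 1] - 1
  accel_episode(s, fs, aligned = TRUE)
}

# Single-axis epoch: the given signal on one axis, (near-)zero elsewhere.
one_axis_epoch <- function(x, fs = 100, axis = c("vt", "ml", "ap")) {
  axis <- match.arg(axis)
  s <- matrix(0, length(x), 3)
  s[, c(vt = 1L, ml = 2L, ap = 3L)[axis]] <- x
  accel_episode(s, fs, aligned = TRUE)
}

# A small two-week paired table in the weekly schema.
paired_table <- function(w1, w2, characteristic = "x") {
  n <- length(w1)
  out <- data.frame(subject = rep(seq_len(n), 2),
                    week = rep(1:2, each = n))
  out[[characteristic]] <- c(w1, w2)
  out
}
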