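# Feature-level synthetic cohort generator under the additive
# variance-component model the weekly analysis assumes.

#' Cohort simulation specification
#'
#' The weekly value of a characteristic for subject i in week j is
#' `x_ij = mu + b_i + u_ij + e_ij`, with independent Gaussian
#' between-subject (`b`), within-subject/week (`u`) and sampling-error
#' (`e`) components. With `days_per_week > 1` the error enters through
#' day-level values: `x_ijk = mu + b_i + u_ij + eps_ijk`, where the
#' day-noise SD is calibrated so the weekly median's sampling variance
#' equals `s2_e` ([median_var_factor()]).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param mu Characteristic mean.
#' @param s2_bs,s2_ws,s2_e Between-subject, within-subject and error
#'   variances (>= 0).
#' @param days_per_week Day-level values per week (default 1: weekly
#'   values drawn directly).
#' @param week2_shift Additive shift applied to week 2 (a simulated
#'   intervention effect; default 0).
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, mu, s2_bs, s2_ws, s2_e,
                        days_per_week = 1L, week2_shift = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, s2_bs >= 0, s2_ws >= 0, s2_e >= 0,
            days_per_week >= 1)
  structure(list(n_subjects = as.integer(n_subjects), mu = mu,
                 s2_bs = s2_bs, s2_ws = s2_ws, s2_e = s2_e,
                 days_per_week = as.integer(days_per_week),
                 week2_shift = week2_shift, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Reference variance-component presets
#'
#' Published agreement and variance-component estimates for the 18
#' daily-life gait characteristics associated with prospective falls
#' (two one-week measurements, 163 community-dwelling older adults):
#' week-effect p, between-week Pearson r, mean, and the
#' between-subject / within-subject / error variance components. Useful
#' as realistic generator parameters and as inputs to
#' [sample_size_grid()].
#'
#' @return A data frame with columns `characteristic`, `p`, `r`, `mean`,
#'   `s2_bs`, `s2_ws`, `s2_e`.
#' @export
gait_variance_presets <- function() {
  tab <- rbind(
    c("composite",            0.64, 0.81, 0.51369, 0.54700, 0.08068,  0.05759),
    c("walking_speed",        0.39, 0.93, 0.45073, 0.01030, 0.00027,  0.00036),
    c("stride_frequency",     0.51, 0.95, 0.82482, 0.01119, 0.00013,  0.00030),
    c("sd_vt",                0.77, 0.92, 1.32658, 0.17858, 0.00061,  0.00733),
    c("sd_ml",                0.18, 0.94, 1.16407, 0.09332, 0.00560,  0.00305),
    c("range_ap",             0.40, 0.91, 7.33318, 7.13497, 0.23150,  0.32894),
    c("stride_autocorr_vt",   0.54, 0.82, 0.37464, 0.01051, 0.00040,  0.00103),
    c("stride_autocorr_ap",   0.63, 0.83, 0.32881, 0.00945, 0.00021,  0.00088),
    c("dominant_amp_vt",      0.68, 0.93, 0.49412, 0.04264, 0.00026,  0.00155),
    c("dominant_amp_ml",      1.00, 0.91, 0.47481, 0.05827, 9.26e-9,  0.00263),
    c("dominant_amp_ap",      0.11, 0.85, 0.51044, 0.02357, 0.00501,  0.00198),
    c("dominant_width_ap",    0.14, 0.80, 0.75841, 0.00611, 0.00167,  0.00075),
    c("ih_vt",                0.19, 0.96, 0.62043, 0.04940, 0.00156,  0.00092),
    c("ih_ml",                0.68, 0.92, 0.64420, 0.06977, 0.00048,  0.00276),
    c("hr_vt",                0.47, 0.90, 1.53576, 0.07348, 0.00211,  0.00406),
    c("lde_vt",               0.75, 0.87, 2.11436, 0.13693, 0.00097,  0.00919),
    c("lde_ap",               0.58, 0.86, 2.19507, 0.09652, 0.00217,  0.00707),
    c("sampen_ml",            0.74, 0.91, 0.31207, 0.00394, 2.07e-5,  0.00018))
  out <- data.frame(characteristic = tab[, 1],
                    p = as.numeric(tab[, 2]), r = as.numeric(tab[, 3]),
                    mean = as.numeric(tab[, 4]), s2_bs = as.numeric(tab[, 5]),
                    s2_ws = as.numeric(tab[, 6]), s2_e = as.numeric(tab[, 7]))
  out
}

#' Cohort spec from a named preset
#'
#' @param preset A `characteristic` name from [gait_variance_presets()]
#'   (e.g. `"composite"`, `"walking_speed"`).
#' @inheritParams cohort_spec
#' @return A [cohort_spec()].
#' @export
cohort_spec_preset <- function(preset, n_subjects, days_per_week = 1L,
                               week2_shift = 0, seed = 1L) {
  tab <- gait_variance_presets()
  row <- tab[tab$characteristic == preset, ]
  if (nrow(row) != 1) {
    stop("unknown preset '", preset, "'; see gait_variance_presets()")
  }
  cohort_spec(n_subjects, mu = row$mean, s2_bs = row$s2_bs,
              s2_ws = row$s2_ws, s2_e = row$s2_e,
              days_per_week = days_per_week, week2_shift = week2_shift,
              seed = seed)
}

#' Simulate a two-week cohort of weekly characteristic values
#'
#' Draws the additive variance-component model of [cohort_spec()]. With
#' `days_per_week > 1`, day-level values are generated with a day-noise
#' SD of `sqrt(s2_e / median_var_factor(K))`, so the weekly median has
#' sampling variance `s2_e` by construction, and the weekly value is the
#' median over days.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `weekly` (data frame `subject, week, value`) and
#'   `days` (data frame `subject, week, day, value`, or `NULL` when
#'   `days_per_week = 1`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  K <- spec$days_per_week
  with_seed(spec$seed, {
    b <- stats::rnorm(n, 0, sqrt(spec$s2_bs))
    u <- matrix(stats::rnorm(2 * n, 0, sqrt(spec$s2_ws)), n, 2)
    base <- spec$mu + b + u + rep(c(0, spec$week2_shift), each = n)
    if (K == 1L) {
      e <- matrix(stats::rnorm(2 * n, 0, sqrt(spec$s2_e)), n, 2)
      weekly_vals <- base + e
      days <- NULL
    } else {
      sd_day <- sqrt(spec$s2_e / unname(median_var_factor(K)))
      eps <- array(stats::rnorm(2 * n * K, 0, sd_day), dim = c(n, 2, K))
      day_vals <- array(rep(base, K), dim = c(n, 2, K)) + eps
      weekly_vals <- cbind(row_medians(day_vals[, 1, , drop = TRUE]),
                           row_medians(day_vals[, 2, , drop = TRUE]))
      days <- data.frame(
        subject = rep(seq_len(n), times = 2L * K),
        week = rep(rep(1:2, each = n), times = K),
        day = rep(seq_len(K), each = 2L * n),
        value = as.vector(day_vals))
      days <- days[order(days$subject, days$week, days$day), ]
      rownames(days) <- NULL
    }
    weekly <- data.frame(subject = rep(seq_len(n), 2),
                         week = rep(1:2, each = n),
                         value = as.vector(weekly_vals))
    weekly <- weekly[order(weekly$subject, weekly$week), ]
    rownames(weekly) <- NULL
    list(weekly = weekly, days = days)
  })
}

#' Between-week correlation implied by the variance components
#'
#' Under the additive model the expected Pearson correlation between the
#' two weekly values of a subject is the between-subject share of total
#' variance, `s2_bs / (s2_bs + s2_ws + s2_e)`.
#'
#' @param spec A [cohort_spec()], a `varcomp`, or a list with `s2_bs`,
#'   `s2_ws`, `s2_e`.
#' @return Scalar correlation in `[0, 1]`.
#' @export
implied_between_week_correlation <- function(spec) {
  tot <- spec$s2_bs + spec$s2_ws + spec$s2_e
  if (tot <= 0) stop("total variance is zero; correlation undefined")
  spec$s2_bs / tot
}
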