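# Repeated-measures variance components and between-week agreement.

#' Between-week agreement of a characteristic
#'
#' Two-way repeated-measures decomposition with subjects and a fixed
#' 2-level week factor: the week effect is tested as
#' `F = MS_week / MS_error` on (1, n-1) degrees of freedom, and the
#' Pearson correlation between the two weekly values quantifies
#' agreement.
#'
#' @param week1,week2 Paired weekly values (complete cases), `n >= 3`.
#' @return List: `F`, `df1`, `df2`, `p_week`, `pearson_r` (NA with a
#'   warning when either week has zero variance), `n`.
#' @export
between_week_agreement <- function(week1, week2) {
  stopifnot(length(week1) == length(week2))
  ok <- is.finite(week1) & is.finite(week2)
  week1 <- week1[ok]; week2 <- week2[ok]
  n <- length(week1)
  if (n < 3) stop("need at least 3 paired subjects")
  ss <- rm_anova_ss(week1, week2)
  Fw <- if (ss$ms_error > 0) ss$ms_week / ss$ms_error else
    (if (ss$ms_week > 0) Inf else 0)
  p <- stats::pf(Fw, 1, n - 1, lower.tail = FALSE)
  r <- if (stats::sd(week1) == 0 || stats::sd(week2) == 0) {
    warning("zero variance within a week: Pearson r undefined")
    NA_real_
  } else {
    stats::cor(week1, week2)
  }
  list(F = Fw, df1 = 1L, df2 = n - 1L, p_week = p, pearson_r = r, n = n)
}

# Balanced two-way (subject x week, J = 2) sums of squares.
rm_anova_ss <- function(week1, week2) {
  n <- length(week1)
  y <- cbind(week1, week2)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  week_means <- colMeans(y)
  ss_subject <- 2 * sum((subj_means - grand)^2)
  ss_week <- n * sum((week_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_error <- ss_total - ss_subject - ss_week
  list(ss_subject = ss_subject, ss_week = ss_week, ss_error = ss_error,
       ss_total = ss_total,
       ms_subject = ss_subject / (n - 1), ms_week = ss_week,
       ms_error = ss_error / (n - 1), grand_mean = grand)
}

#' Estimate variance components of a weekly characteristic
#'
#' Method-of-moments estimates from the balanced two-way decomposition
#' over `n` subjects and 2 weeks:
#' `s2_bs = max(0, (MS_subject - MS_error) / 2)`. `MS_error` pools the
#' genuine week-to-week (within-subject) variance with the sampling
#' error of the weekly median; the two are only separable when day-level
#' values are supplied. With `day_level` data the sampling variance of
#' each weekly median is estimated (see `method`), averaged over
#' subject-weeks to give `s2_e`, and `s2_ws = max(0, MS_error - s2_e)`.
#' Without day-level data `s2_e = MS_error`, `s2_ws = 0`, and
#' `separable_error = FALSE`. Negative moment estimates are truncated at
#' zero and flagged, never silently.
#'
#' @param table Weekly table (schema of [weekly_median_table()] /
#'   [simulate_cohort()]).
#' @param characteristic Column to analyse.
#' @param day_level Optional data frame `subject, week, day, value` of
#'   the day-level values underlying each weekly median.
#' @param method Sampling-variance estimator for the weekly median:
#'   `"moment"` (default) scales the unbiased within-subject-week day
#'   variance by the Monte-Carlo variance factor of a K-point normal
#'   median ([median_var_factor()]); `"bootstrap"` uses a seeded
#'   `n_boot`-resample bootstrap per subject-week (upward-biased at
#'   small day counts; see the package vignette).
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return An object of class `varcomp`: characteristic, `mean`,
#'   `s2_bs`, `s2_ws`, `s2_e`, `s2_total`, `p_week`, `pearson_r`, `F`,
#'   `n_subjects`, `separable_error`, `truncated`, `n_excluded`.
#' @export
variance_components <- function(table, characteristic, day_level = NULL,
                                method = c("moment", "bootstrap"),
                                n_boot = 200, seed = 1L) {
  method <- match.arg(method)
  pc <- paired_complete(table, characteristic)
  n_all <- length(unique(table$subject))
  n <- nrow(pc)
  if (n < 3) stop("need at least 3 complete-case subjects")
  n_excluded <- n_all - n
  if (n_excluded > 0) {
    message(sprintf("variance_components: %d subject(s) without both weeks excluded",
                    n_excluded))
  }
  ss <- rm_anova_ss(pc$week1, pc$week2)
  agree <- between_week_agreement(pc$week1, pc$week2)
  s2_bs_raw <- (ss$ms_subject - ss$ms_error) / 2
  truncated <- s2_bs_raw < 0
  s2_bs <- max(0, s2_bs_raw)

  if (!is.null(day_level)) {
    dl <- day_level[day_level$subject %in% pc$subject, , drop = FALSE]
    s2_e <- median_sampling_variance(dl, method = method, n_boot = n_boot,
                                     seed = seed)
    s2_ws_raw <- ss$ms_error - s2_e
    truncated <- truncated || s2_ws_raw < 0
    s2_ws <- max(0, s2_ws_raw)
    separable <- TRUE
  } else {
    s2_e <- ss$ms_error
    s2_ws <- 0
    separable <- FALSE
  }
  if (truncated) {
    warning("negative method-of-moments component truncated to 0")
  }
  structure(list(characteristic = characteristic, mean = ss$grand_mean,
                 s2_bs = s2_bs, s2_ws = s2_ws, s2_e = s2_e,
                 s2_total = s2_bs + s2_ws + s2_e,
                 ms_subject = ss$ms_subject, ms_error = ss$ms_error,
                 F = agree$F, p_week = agree$p_week,
                 pearson_r = agree$pearson_r, n_subjects = n,
                 n_excluded = n_excluded, separable_error = separable,
                 truncated = truncated, method = method),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("<varcomp> %s (n = %d)\n", x$characteristic, x$n_subjects))
  cat(sprintf("  mean %.5f | s2_bs %.5f  s2_ws %.5f  s2_e %.5f  (total %.5f)%s\n",
              x$mean, x$s2_bs, x$s2_ws, x$s2_e, x$s2_total,
              if (x$separable_error) "" else "  [ws/e not separated]"))
  cat(sprintf("  week effect F = %.4f, p = %.3f | between-week r = %.3f\n",
              x$F, x$p_week, x$pearson_r))
  invisible(x)
}

# Mean (over subject-weeks) sampling variance of the weekly median,
# estimated from day-level values.
median_sampling_variance <- function(day_level, method = "moment",
                                     n_boot = 200, seed = 1L) {
  stopifnot(all(c("subject", "week", "day", "value") %in% names(day_level)))
  day_level <- day_level[is.finite(day_level$value), , drop = FALSE]
  key <- interaction(day_level$subject, day_level$week, drop = TRUE)
  groups <- split(day_level$value, key)
  ks <- lengths(groups)
  if (any(ks < 2)) {
    groups <- groups[ks >= 2]
    ks <- ks[ks >= 2]
  }
  if (!length(groups)) stop("day-level data needs >= 2 days per subject-week")
  if (method == "moment") {
    # unbiased day variance scaled by the K-point-median variance factor
    vars <- vapply(groups, stats::var, numeric(1))
    mean(vars * median_var_factor(ks)[as.character(ks)])
  } else {
    uk <- sort(unique(ks))
    total <- 0; count <- 0
    with_seed(seed, {
      for (k in uk) {
        gs <- groups[ks == k]
        vals <- unlist(gs, use.names = FALSE)
        ng <- length(gs)
        # one resample-index matrix per day count, shared across groups
        idx <- matrix(sample.int(k, k * n_boot * ng, replace = TRUE), ncol = k)
        offs <- rep((seq_len(ng) - 1L) * k, each = n_boot)
        med <- row_medians(matrix(vals[idx + offs], ncol = k))
        gmed <- matrix(med, nrow = n_boot)
        total <- total + sum(apply(gmed, 2, stats::var))
        count <- count + ng
      }
    })
    total / count
  }
}

#' Variance factor of the median of K standard normal values
#'
#' `Var(median(X_1..X_K))` for iid standard normals, estimated once per
#' `K` by seeded Monte Carlo (100,000 draws) and cached for the session.
#' Used both to calibrate the day-level noise of the cohort generator
#' and by the moment estimator of the weekly median's sampling variance.
#'
#' @param k Integer vector of day counts.
#' @param n_mc Monte-Carlo draws.
#' @return Named numeric vector of factors, one per unique `k`
#'   (`k = 1` gives exactly 1).
#' @export
median_var_factor <- function(k, n_mc = 1e5) {
  k <- sort(unique(as.integer(k)))
  out <- stats::setNames(numeric(length(k)), as.character(k))
  for (i in seq_along(k)) {
    ki <- k[i]
    key <- as.character(ki)
    if (!is.null(.gq_cache[[key]])) {
      out[i] <- .gq_cache[[key]]
      next
    }
    val <- if (ki == 1L) 1 else with_seed(20200618L + ki, {
      stats::var(row_medians(matrix(stats::rnorm(n_mc * ki), ncol = ki)))
    })
    assign(key, val, envir = .gq_cache)
    out[i] <- val
  }
  out
}

.gq_cache <- new.env(parent = emptyenv())

#' Variance-component report over all characteristics
#'
#' Runs [variance_components()] for each characteristic column of a
#' weekly table, mirroring the per-characteristic reporting layout of a
#' test-retest study (mean, components, week-effect p, between-week r).
#'
#' @param table Weekly table.
#' @param characteristics Columns to analyse (default: all non-key,
#'   non-count columns).
#' @param day_level Optional day-level data with a `characteristic`
#'   column (long format) or a single-characteristic `value` column.
#' @inheritParams variance_components
#' @return A list of `varcomp` objects, named by characteristic.
#' @export
varcomp_report <- function(table, characteristics = NULL, day_level = NULL,
                           method = c("moment", "bootstrap"), n_boot = 200,
                           seed = 1L) {
  method <- match.arg(method)
  if (is.null(characteristics)) {
    characteristics <- setdiff(names(table), c("subject", "week"))
    characteristics <- characteristics[!startsWith(characteristics, "n_epochs_")]
  }
  out <- lapply(characteristics, function(ch) {
    dl <- day_level
    if (!is.null(dl) && "characteristic" %in% names(dl)) {
      dl <- dl[dl$characteristic == ch, , drop = FALSE]
      if (!nrow(dl)) dl <- NULL
    }
    tryCatch(variance_components(table, ch, day_level = dl, method = method,
                                 n_boot = n_boot, seed = seed),
             error = function(e) {
               warning(sprintf("%s: %s", ch, conditionMessage(e)))
               NULL
             })
  })
  names(out) <- characteristics
  out[!vapply(out, is.null, logical(1))]
}

#' Write / read a variance-component report as JSON
#'
#' @param report List of `varcomp` objects from [varcomp_report()].
#' @param path File path.
#' @export
write_varcomp_json <- function(report, path) {
  ser <- lapply(report, function(v) v[setdiff(names(v), "characteristic")])
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_varcomp_json
#' @export
read_varcomp_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    v <- as.list(raw[[nm]])
    v$characteristic <- nm
    structure(v, class = "varcomp")
  })
  stats::setNames(out, names(raw))
}
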