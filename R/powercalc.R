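# Required participants for a paired pre/post comparison of a weekly
# gait characteristic, from its variance components.

#' Specification for a sample-size calculation
#'
#' @param d Standardized effect size (Cohen's d, > 0); the raw effect is
#'   `d * sqrt(s2_total)`.
#' @param r_assumed Assumed within-subject (pre/post) correlation in
#'   `[0, 1)`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Desired power `1 - beta` (default 0.8).
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(d, r_assumed, alpha = 0.05, power = 0.8) {
  stopifnot(d > 0, r_assumed >= 0, r_assumed < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  structure(list(d = d, r_assumed = r_assumed, alpha = alpha, power = power),
            class = "power_spec")
}

# Right-hand side of the repeated-measures sample-size relation:
# n >= 2 s_S^2 (1 - r s_BS^2 / s_S^2) (t_{n-1,1-beta} + t_{n-1,1-alpha/2})^2 / Delta^2,
# with Delta = d sqrt(s_S^2), so the variance scale cancels.
required_n_rhs <- function(n, rho, spec) {
  tq <- stats::qt(spec$power, n - 1) + stats::qt(1 - spec$alpha / 2, n - 1)
  2 * (1 - spec$r_assumed * rho) * tq^2 / spec$d^2
}

#' Required number of participants (paired pre/post design)
#'
#' Solves the repeated-measures sample-size relation for the smallest
#' integer `n >= 2` satisfying `n >= f(n)`, where
#' `f(n) = 2 (1 - r * s2_bs / s2_total) (t_{n-1,1-beta} + t_{n-1,1-alpha/2})^2 / d^2`.
#' Because the effect is standardized by the total SD
#' (`Delta = d * sqrt(s2_total)`), the result depends on the variance
#' components only through the ratio `rho = s2_bs / s2_total`. `f` is
#' decreasing in `n`, so the smallest such `n` is well defined; the
#' search starts from the normal-quantile closed form and scans outward.
#'
#' @param s2_total Total variance of the characteristic (> 0).
#' @param s2_bs Between-subject variance, `0 <= s2_bs <= s2_total`.
#' @param spec A [power_spec()].
#' @return Integer sample size, `>= 2`.
#' @export
required_n <- function(s2_total, s2_bs, spec) {
  stopifnot(inherits(spec, "power_spec"), s2_total > 0, s2_bs >= 0)
  if (s2_bs > s2_total) stop("s2_bs exceeds s2_total")
  rho <- s2_bs / s2_total
  z <- stats::qnorm(spec$power) + stats::qnorm(1 - spec$alpha / 2)
  n0 <- ceiling(2 * (1 - spec$r_assumed * rho) * z^2 / spec$d^2)
  n <- max(2L, as.integer(n0))
  while (n > 2L && (n - 1L) >= required_n_rhs(n - 1L, rho, spec)) n <- n - 1L
  while (n < required_n_rhs(n, rho, spec)) n <- n + 1L
  n
}

#' Sample-size grid over effect sizes and assumed correlations
#'
#' Evaluates [required_n()] on the cross product of effect sizes and
#' assumed within-subject correlations for each characteristic's
#' variance components. Defaults cover small/medium/large effects
#' (d = 0.3, 0.5, 0.8) at r = 0.3, 0.6, 0.9.
#'
#' @param varcomps A list of `varcomp` objects (from [varcomp_report()])
#'   or a single `varcomp`.
#' @param d_list,r_list Grid values.
#' @param alpha,power Passed to [power_spec()].
#' @return A long data frame of class `power_grid`: characteristic, `d`,
#'   `r`, `n`, plus the `s2_total`/`s2_bs` used; failed cells carry `NA`
#'   with the error message in `note`.
#' @export
sample_size_grid <- function(varcomps, d_list = c(0.3, 0.5, 0.8),
                             r_list = c(0.3, 0.6, 0.9),
                             alpha = 0.05, power = 0.8) {
  if (inherits(varcomps, "varcomp")) varcomps <- list(varcomps)
  rows <- list()
  for (v in varcomps) {
    for (d in d_list) {
      for (r in r_list) {
        n <- NA_integer_; note <- ""
        res <- tryCatch(
          required_n(v$s2_total, v$s2_bs, power_spec(d, r, alpha, power)),
          error = function(e) conditionMessage(e))
        if (is.numeric(res)) n <- res else note <- res
        rows[[length(rows) + 1L]] <-
          data.frame(characteristic = v$characteristic, d = d, r = r, n = n,
                     s2_total = v$s2_total, s2_bs = v$s2_bs, note = note)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_grid", class(out))
  out
}

#' Reshape a sample-size grid to the wide per-characteristic layout
#'
#' One row per characteristic, one column per (d, r) combination, column
#' names `n_d<d>_r<r>`.
#'
#' @param grid A `power_grid` from [sample_size_grid()].
#' @return A wide data frame.
#' @export
grid_to_table <- function(grid) {
  grid$cell <- sprintf("n_d%g_r%g", grid$d, grid$r)
  wide <- stats::reshape(
    grid[, c("characteristic", "cell", "n")],
    idvar = "characteristic", timevar = "cell", direction = "wide")
  names(wide) <- sub("^n\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
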