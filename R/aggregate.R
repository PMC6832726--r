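# Weekly median aggregation of epoch-level characteristics.

#' Weekly median characteristic table
#'
#' Collapses epoch-level feature rows to one row per (subject, week): the
#' median over valid epochs, per characteristic. A cell is set to missing
#' when fewer than `min_epochs` valid (non-missing) epoch values support
#' it; the supporting count is reported in an `n_epochs_<characteristic>`
#' column. Medians are computed per characteristic independently, so a
#' cell can be missing for one characteristic but present for another.
#'
#' @param epoch_rows Data frame as produced by [extract_features()]
#'   (possibly row-bound over many episodes): subject, week, valid flag,
#'   characteristic columns.
#' @param min_epochs Minimum number of valid epoch values per cell.
#' @return Data frame keyed by (subject, week) with characteristic
#'   medians and epoch counts; empty input yields an empty table.
#' @export
weekly_median_table <- function(epoch_rows, min_epochs = 10) {
  stopifnot(min_epochs >= 1)
  id_cols <- c("subject", "week", "day", "epoch", "valid")
  chars <- setdiff(names(epoch_rows), id_cols)
  if (nrow(epoch_rows) == 0) {
    out <- epoch_rows[0, c("subject", "week", chars), drop = FALSE]
    for (ch in chars) out[[paste0("n_epochs_", ch)]] <- integer(0)
    return(out)
  }
  valid <- epoch_rows[epoch_rows$valid %in% TRUE, , drop = FALSE]
  key <- interaction(epoch_rows$subject, epoch_rows$week, drop = TRUE)
  groups <- unique(epoch_rows[, c("subject", "week")])
  groups <- groups[order(groups$subject, groups$week), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- valid[valid$subject == groups$subject[i] &
                 valid$week == groups$week[i], , drop = FALSE]
    row <- data.frame(subject = groups$subject[i], week = groups$week[i])
    for (ch in chars) {
      v <- g[[ch]]
      v <- v[is.finite(v)]
      row[[ch]] <- if (length(v) >= min_epochs) stats::median(v) else NA_real_
      row[[paste0("n_epochs_", ch)]] <- length(v)
    }
    row
  })
  do.call(rbind, rows)
}

#' Restrict a weekly table to two-week complete cases
#'
#' Keeps subjects with a non-missing value of `characteristic` in both
#' weeks (the paired analyses require complete cases) and returns the
#' paired values.
#'
#' @param table Weekly table from [weekly_median_table()] (or the same
#'   schema from [simulate_cohort()]).
#' @param characteristic Column name to pair.
#' @return A data frame with columns `subject`, `week1`, `week2`.
#' @export
paired_complete <- function(table, characteristic) {
  stopifnot(characteristic %in% names(table))
  w1 <- table[table$week == 1, c("subject", characteristic)]
  w2 <- table[table$week == 2, c("subject", characteristic)]
  names(w1)[2] <- "week1"; names(w2)[2] <- "week2"
  m <- merge(w1, w2, by = "subject")
  m[is.finite(m$week1) & is.finite(m$week2), , drop = FALSE]
}
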