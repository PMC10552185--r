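#' Per-peptide, per-timepoint uptake differences between two states
#'
#' Matches peptides and timepoints between a state table and a reference
#' table (both in the [uptake_table()] dialect), computes
#' \code{delta = mean_state - mean_reference} with propagated replicate
#' error \code{delta_sd = sqrt(sd_state^2 + sd_ref^2)}, and flags
#' significance by the magnitude threshold (see [flag_significant()]).
#' Negative differences denote protection (decreased exchange in the state
#' relative to the reference); positive differences denote deprotection.
#'
#' Unmatched (peptide, timepoint) entries are skipped with a message. Rows
#' are ordered from the N- to the C-terminus and then by exchange time, the
#' order difference plots are drawn in.
#'
#' @param state_table,reference_table Uptake tables from [uptake_table()].
#' @param threshold Significance threshold in Da (default 0.5); strict
#'   inequality, see [flag_significant()].
#' @param welch If \code{TRUE}, annotate each row with a Welch two-sample
#'   t-test p-value computed from the summary statistics (off by default; the
#'   magnitude rule is the primary criterion).
#' @return A \code{data.frame} with columns \code{peptide_id}, \code{start},
#'   \code{end}, \code{t_ex_min}, \code{delta_Da}, \code{delta_sd_Da},
#'   \code{significant}, \code{direction} (and \code{welch_p} if requested).
#' @export
difference_records <- function(state_table, reference_table, threshold = 0.5,
                               welch = FALSE) {
  m <- merge(state_table, reference_table,
             by = c("peptide_id", "start", "end", "t_ex_min"),
             suffixes = c("_state", "_ref"))
  if (nrow(m) == 0) stop("no common (peptide, timepoint) entries", call. = FALSE)
  n_skipped <- nrow(state_table) + nrow(reference_table) - 2L * nrow(m)
  if (n_skipped > 0) {
    message(n_skipped, " unmatched uptake row(s) skipped")
  }
  out <- data.frame(peptide_id = m$peptide_id, start = m$start, end = m$end,
                    t_ex_min = m$t_ex_min,
                    delta_Da = m$uptake_mean_Da_state - m$uptake_mean_Da_ref,
                    delta_sd_Da = sqrt(m$uptake_sd_Da_state^2 + m$uptake_sd_Da_ref^2))
  out <- flag_significant(out, threshold = threshold)
  if (welch) {
    out$welch_p <- mapply(.welch_p, m$uptake_mean_Da_state, m$uptake_sd_Da_state,
                          m$n_state, m$uptake_mean_Da_ref, m$uptake_sd_Da_ref,
                          m$n_ref)
  }
  out <- out[order(out$start, out$end, out$t_ex_min), ]
  rownames(out) <- NULL
  out
}

#' Flag significant uptake differences
#'
#' A difference is significant when its magnitude strictly exceeds the
#' threshold (default 0.5 Da); a difference of exactly 0.5 Da is not
#' significant. Direction is \code{"deprotection"} for positive significant
#' deltas, \code{"protection"} for negative ones, \code{"none"} otherwise.
#'
#' @param records A \code{data.frame} with a \code{delta_Da} column (e.g. from
#'   [difference_records()]).
#' @param threshold Magnitude threshold in Da, default 0.5.
#' @return \code{records} with \code{significant} and \code{direction}
#'   columns set.
#' @export
flag_significant <- function(records, threshold = 0.5) {
  records$significant <- abs(records$delta_Da) > threshold
  records$direction <- ifelse(!records$significant, "none",
                              ifelse(records$delta_Da > 0, "deprotection",
                                     "protection"))
  records
}

# Welch t from summary stats; sd may be 0 when n = 1
.welch_p <- function(m1, s1, n1, m2, s2, n2) {
  v <- s1^2 / n1 + s2^2 / n2
  if (v <= 0 || n1 < 2 || n2 < 2) return(NA_real_)
  tt <- (m1 - m2) / sqrt(v)
  df <- v^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tt), df)
}
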