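#' Filter a peptide identification table
#'
#' Applies the standard peptide-level quality filters used before uptake
#' analysis. All thresholds are inclusive (a record exactly at a cutoff is
#' kept) and a record must satisfy every filter to survive.
#'
#' @param records A \code{data.frame} with columns \code{sequence},
#'   \code{intensity}, \code{n_products}, \code{n_files},
#'   \code{mass_error_ppm} (signed).
#' @param min_intensity Minimum ion intensity (default 5000).
#' @param min_len,max_len Inclusive peptide length bounds (default 5-25).
#' @param max_ppm Maximum absolute mass error in ppm (default 10).
#' @param min_products Minimum number of fragment products (default 1).
#' @param file_threshold Minimum number of acquisitions identifying the
#'   peptide (default 2).
#' @return The filtered \code{data.frame} (possibly zero rows).
#' @export
filter_peptide_table <- function(records, min_intensity = 5000, min_len = 5,
                                 max_len = 25, max_ppm = 10, min_products = 1,
                                 file_threshold = 2) {
  if (nrow(records) == 0) return(records)
  len <- nchar(records$sequence)
  keep <- records$intensity >= min_intensity &
    len >= min_len & len <= max_len &
    abs(records$mass_error_ppm) <= max_ppm &
    records$n_products >= min_products &
    records$n_files >= file_threshold
  records[keep, , drop = FALSE]
}

#' Deuterium uptake from a pair of envelopes
#'
#' Uptake (Da) is the neutral-mass centroid of the deuterated envelope minus
#' the centroid of the corresponding undeuterated envelope of the same
#' peptide and charge. Values are reported uncorrected for the effective
#' label fraction (see [effective_label_fraction()]); pass
#' \code{correct_label_fraction} to divide by it.
#'
#' @param deut,undeut [spectral_envelope()] objects for the same peptide and
#'   charge.
#' @param correct_label_fraction Optional fraction in (0, 1]; if supplied the
#'   raw uptake is divided by it. Default \code{NULL} (no correction).
#' @return Deuterium uptake in Da.
#' @export
deuterium_uptake <- function(deut, undeut, correct_label_fraction = NULL) {
  pd <- attr(deut, "peptide"); pu <- attr(undeut, "peptide")
  if (!identical(pd$sequence, pu$sequence) || pd$charge != pu$charge) {
    stop("envelopes are from different peptides or charge states", call. = FALSE)
  }
  up <- centroid(deut) - centroid(undeut)
  if (!is.null(correct_label_fraction)) {
    stopifnot(correct_label_fraction > 0, correct_label_fraction <= 1)
    up <- up / correct_label_fraction
  }
  up
}

#' Replicate mean and standard deviation
#'
#' Arithmetic mean and sample (n-1) standard deviation of replicate uptake
#' values; the SD is 0 for a single replicate.
#'
#' @param uptakes Numeric vector of uptake values (Da), length >= 1.
#' @return Named numeric vector \code{c(mean, sd)}.
#' @export
replicate_stats <- function(uptakes) {
  if (length(uptakes) == 0) stop("at least one replicate required", call. = FALSE)
  s <- if (length(uptakes) == 1L) 0 else stats::sd(uptakes)
  c(mean = mean(uptakes), sd = s)
}

#' Labeling conditions of a deuterium-exchange experiment
#'
#' @param sample_volume,buffer_volume Volumes mixed (same units, e.g. uL);
#'   defaults 3 and 27 (a 1:10 dilution into labeling buffer).
#' @param d2o_purity D2O fraction of the labeling buffer, default 0.99.
#' @param temperature Labeling temperature in Celsius (metadata).
#' @param t_ex_grid Exchange timepoints in minutes, default \code{c(1, 10, 30)}.
#' @param n_replicates Replicates per condition, default 3.
#' @return A list of class \code{"labeling_conditions"}.
#' @export
labeling_conditions <- function(sample_volume = 3, buffer_volume = 27,
                                d2o_purity = 0.99, temperature = 25,
                                t_ex_grid = c(1, 10, 30), n_replicates = 3L) {
  stopifnot(sample_volume > 0, buffer_volume >= 0,
            d2o_purity > 0, d2o_purity <= 1)
  structure(list(sample_volume = sample_volume, buffer_volume = buffer_volume,
                 d2o_purity = d2o_purity, temperature = temperature,
                 t_ex_grid = t_ex_grid, n_replicates = as.integer(n_replicates)),
            class = "labeling_conditions")
}

#' Effective deuterium label fraction
#'
#' Fraction of solvent exchangeable positions exposed to deuterium given the
#' dilution and D2O purity:
#' \code{buffer / (sample + buffer) * purity}. For the default 3 uL into
#' 27 uL of 99\% D2O this is 27/30 x 0.99 = 0.891 (nominally "90\%"
#' deuteration).
#'
#' @param conditions A [labeling_conditions()] object.
#' @return Fraction in \code{[0, 1]}.
#' @export
effective_label_fraction <- function(conditions) {
  with(conditions,
       buffer_volume / (sample_volume + buffer_volume) * d2o_purity)
}

#' Build a per-peptide uptake table from envelopes
#'
#' Pairs every deuterated envelope with the undeuterated reference of the
#' same peptide/charge, computes centroid-difference uptake per replicate and
#' aggregates replicate statistics. Output follows the state-file CSV dialect:
#' one row per (peptide, state, t_ex) with columns \code{peptide_id},
#' \code{sequence}, \code{start}, \code{end}, \code{state}, \code{t_ex_min},
#' \code{uptake_mean_Da}, \code{uptake_sd_Da}, \code{n}.
#'
#' @param envelopes List of deuterated [spectral_envelope()] objects
#'   (replicates across states/timepoints).
#' @param undeuterated Named list of undeuterated reference envelopes, names
#'   \code{"start-end"} peptide ids; or a single envelope when all deuterated
#'   envelopes share one peptide.
#' @param correct_label_fraction See [deuterium_uptake()].
#' @return The uptake \code{data.frame}.
#' @export
uptake_table <- function(envelopes, undeuterated, correct_label_fraction = NULL) {
  if (inherits(undeuterated, "spectral_envelope")) {
    pep <- attr(undeuterated, "peptide")
    undeuterated <- stats::setNames(list(undeuterated),
                                    sprintf("%s-%s", pep$start, pep$end))
  }
  meta <- lapply(envelopes, function(e) {
    pep <- attr(e, "peptide")
    data.frame(peptide_id = sprintf("%s-%s", pep$start, pep$end),
               sequence = pep$sequence, start = pep$start, end = pep$end,
               state = attr(e, "state"), t_ex_min = attr(e, "t_ex"))
  })
  meta <- do.call(rbind, meta)
  meta$uptake <- vapply(envelopes, function(e) {
    pep <- attr(e, "peptide")
    ref <- undeuterated[[sprintf("%s-%s", pep$start, pep$end)]]
    if (is.null(ref)) return(NA_real_)
    deuterium_uptake(e, ref, correct_label_fraction)
  }, numeric(1))
  meta <- meta[!is.na(meta$uptake), , drop = FALSE]
  key <- interaction(meta$peptide_id, meta$state, meta$t_ex_min, drop = TRUE)
  out <- do.call(rbind, lapply(split(meta, key), function(g) {
    st <- replicate_stats(g$uptake)
    data.frame(peptide_id = g$peptide_id[1], sequence = g$sequence[1],
               start = g$start[1], end = g$end[1], state = g$state[1],
               t_ex_min = g$t_ex_min[1],
               uptake_mean_Da = unname(st["mean"]),
               uptake_sd_Da = unname(st["sd"]), n = nrow(g))
  }))
  out <- out[order(out$start, out$end, out$state, out$t_ex_min), ]
  rownames(out) <- NULL
  out
}
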