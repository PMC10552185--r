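#' @export
print.bimodal_fit <- function(x, ...) {
  cat("Bimodal deconvolution fit\n")
  pep <- attr(x$envelope, "peptide")
  if (!is.na(pep$sequence)) {
    cat(sprintf("  peptide %d-%d %s (+%d), t_ex = %s min\n", pep$start, pep$end,
                pep$sequence, pep$charge, format(attr(x$envelope, "t_ex"))))
  }
  cat(sprintf("  classification: %s (F-test p = %.3g)\n", x$classification, x$f_p))
  if (x$classification == "bimodal") {
    cat(sprintf("  low-exchanging:  %.2f Da  %.1f%%\n", x$uptake_low, x$frac_low_pct))
    cat(sprintf("  high-exchanging: %.2f Da  %.1f%%\n", x$uptake_high, x$frac_high_pct))
  }
  invisible(x)
}

#' @export
summary.bimodal_fit <- function(object, ...) {
  out <- data.frame(
    classification = object$classification,
    f_p = object$f_p, reg_ci = object$reg_ci, delta_chi = object$delta_chi,
    separation_Da = object$separation,
    uptake_low_Da = object$uptake_low, frac_low_pct = object$frac_low_pct,
    uptake_high_Da = object$uptake_high, frac_high_pct = object$frac_high_pct,
    single_p = object$single$p_hat, single_rss = object$single$rss,
    double_rss = object$double$rss, snr = object$snr)
  class(out) <- c("summary.bimodal_fit", "data.frame")
  out
}

#' @export
print.summary.bimodal_fit <- function(x, ...) {
  print.data.frame(format(x, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bimodal_fit <- function(object, ...) {
  c(p_low = object$double$p_low, p_high = object$double$p_high,
    frac_low = object$double$frac_low, p_single = object$single$p_hat)
}

#' @export
fitted.bimodal_fit <- function(object, ...) {
  object$double$fitted
}

#' @export
residuals.bimodal_fit <- function(object, model = c("double", "single"), ...) {
  model <- match.arg(model)
  object$envelope$intensity - object[[model]]$fitted
}

#' @param x A \code{"bimodal_fit"} object.
#' @param ... Passed to [graphics::plot()].
#' @describeIn bimodal_fit Stick spectrum with the single (dashed) and
#'   double (solid) model overlays.
#' @export
plot.bimodal_fit <- function(x, ...) {
  env <- x$envelope
  graphics::plot(env$mz, env$intensity, type = "h", col = "grey40",
                 xlab = "m/z (Th)", ylab = "intensity", ...)
  graphics::lines(env$mz, x$single$fitted, lty = 2, col = "steelblue")
  graphics::lines(env$mz, x$double$fitted, lty = 1, col = "firebrick")
  graphics::legend("topright", bty = "n", lty = c(2, 1),
                   col = c("steelblue", "firebrick"),
                   legend = c("single binomial", "double binomial"))
  invisible(x)
}

#' Bimodal report over a set of envelopes
#'
#' Runs [bimodal_fit()] on every envelope and assembles the one-row-per-
#' (peptide, state, timepoint, replicate) report table with the
#' classification, F-test p, confidence-of-fit, delta-chi, separation, and
#' the per-population uptakes and percentages (NA for non-bimodal spectra).
#'
#' @param envelopes List of [spectral_envelope()] objects.
#' @param thresholds A [bimodal_thresholds()] list.
#' @param intensity_cv Assumed multiplicative noise CV, see [bimodal_fit()].
#' @return A \code{data.frame}.
#' @export
bimodal_report <- function(envelopes, thresholds = bimodal_thresholds(),
                           intensity_cv = 0) {
  if (inherits(envelopes, "spectral_envelope")) envelopes <- list(envelopes)
  rows <- lapply(envelopes, function(e) {
    fit <- bimodal_fit(e, thresholds = thresholds, intensity_cv = intensity_cv)
    pep <- attr(e, "peptide")
    bim <- fit$classification == "bimodal"
    data.frame(peptide_id = sprintf("%s-%s", pep$start, pep$end),
               state = attr(e, "state"), t_ex_min = attr(e, "t_ex"),
               replicate = attr(e, "replicate"),
               classification = fit$classification,
               f_p = fit$f_p, reg_ci = fit$reg_ci, delta_chi = fit$delta_chi,
               separation_Da = fit$separation,
               uptake_low_Da = if (bim) fit$uptake_low else NA_real_,
               frac_low_pct = if (bim) fit$frac_low_pct else NA_real_,
               uptake_high_Da = if (bim) fit$uptake_high else NA_real_,
               frac_high_pct = if (bim) fit$frac_high_pct else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
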