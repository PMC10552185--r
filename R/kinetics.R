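# Population kinetics (ligand-release half-life) and Michaelis-Menten
# analysis of the linked phosphodiesterase assay.

#' Fit an exponential release half-life to bound-population fractions
#'
#' One-parameter exponential decay \code{f(t) = exp(-k t)} with
#' \code{f(0) = 1} fixed, fitted by least squares on the log-transformed
#' fractions weighted by exchange time; the half-life is \code{ln 2 / k}.
#' The time-weighting makes the two-timepoint estimate from population
#' fractions well-posed while favouring the longer, better-determined
#' timepoints.
#'
#' @param times Exchange times (min), positive.
#' @param bound_fracs Bound-population fractions in \code{[0, 1]}, same
#'   length.
#' @return An object of class \code{"release_fit"}: \code{times},
#'   \code{bound_frac}, \code{k} (min^-1), \code{t_half} (min;
#'   \code{Inf} with status \code{"no_release"} when all fractions are 1),
#'   \code{fit_residual} (RSS on the log scale), \code{status}.
#' @examples
#' fit <- release_fit(c(10, 30), c(0.856, 0.65))
#' fit$t_half  # ~48 min
#' @export
release_fit <- function(times, bound_fracs) {
  stopifnot(length(times) == length(bound_fracs), length(times) >= 1,
            all(times > 0), all(bound_fracs >= 0), all(bound_fracs <= 1))
  if (all(bound_fracs >= 1)) {
    return(structure(list(times = times, bound_frac = bound_fracs,
                          k = 0, t_half = Inf, fit_residual = 0,
                          status = "no_release"),
                     class = "release_fit"))
  }
  keep <- bound_fracs > 0  # zero fractions carry no log-scale information
  t <- times[keep]; f <- bound_fracs[keep]
  w <- t
  k <- -sum(w * t * log(f)) / sum(w * t^2)
  res <- sum(w * (log(f) + k * t)^2)
  structure(list(times = times, bound_frac = bound_fracs, k = k,
                 t_half = log(2) / k, fit_residual = res, status = "ok"),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  if (x$status == "no_release") {
    cat("Release kinetics: no release detected (all fractions at 1)\n")
  } else {
    cat(sprintf("Release kinetics: k = %.4f min^-1, t1/2 = %.1f min (%d timepoints)\n",
                x$k, x$t_half, length(x$times)))
  }
  invisible(x)
}

#' @export
coef.release_fit <- function(object, ...) {
  c(k = object$k, t_half = object$t_half)
}

#' @param object A \code{"release_fit"}.
#' @param newdata Optional list/data.frame with a \code{times} element.
#' @param ... Unused.
#' @describeIn release_fit Predicted bound fraction at new times.
#' @export
predict.release_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else newdata$times
  exp(-object$k * t)
}

#' Fold change between two half-lives
#'
#' @param t_half_a,t_half_b Half-lives (same units), both > 0.
#' @return \code{t_half_a / t_half_b}.
#' @export
fold_change <- function(t_half_a, t_half_b) {
  if (t_half_b <= 0 || t_half_a <= 0) stop("half-lives must be > 0", call. = FALSE)
  t_half_a / t_half_b
}

#' Michaelis-Menten fit of initial-rate data
#'
#' Nonlinear least squares of \code{v = Vmax * S / (Km + S)} to initial rates
#' over a substrate grid, with standard errors from the fit covariance.
#' Replicate rates at the same substrate concentration are averaged before
#' fitting by default (set \code{average_replicates = FALSE} to fit all
#' points). The turnover number is derived from the fitted Vmax and the
#' enzyme concentration (see [kcat_from_vmax()]).
#'
#' @param substrate Substrate concentrations (uM); at least 4 distinct values
#'   spanning the expected Km.
#' @param rate Initial rates (uM/min), same length.
#' @param enzyme_nM Enzyme concentration (nM), default 1.
#' @param variant Label for the enzyme variant (metadata).
#' @param average_replicates Average duplicate substrate levels before
#'   fitting (default TRUE).
#' @return An object of class \code{"mm_fit"}: \code{km}, \code{vmax},
#'   \code{kcat} (s^-1), \code{se_km}, \code{se_vmax}, \code{enzyme_nM},
#'   \code{substrate}, \code{rates}, \code{nls} (the underlying fit),
#'   \code{variant}, \code{converged}.
#' @examples
#' s <- c(0.25, 0.5, 1, 2, 5, 10)
#' v <- 0.12 * s / (1.13 + s)
#' fit <- mm_fit(s, v)
#' coef(fit)
#' @export
mm_fit <- function(substrate, rate, enzyme_nM = 1, variant = "enzyme",
                   average_replicates = TRUE) {
  stopifnot(length(substrate) == length(rate), all(substrate > 0))
  if (length(unique(substrate)) < 4) {
    stop("at least 4 distinct substrate concentrations are required", call. = FALSE)
  }
  s_all <- substrate; v_all <- rate
  if (average_replicates) {
    v_all <- tapply(rate, substrate, mean)
    s_all <- as.numeric(names(v_all))
    v_all <- as.numeric(v_all)
  }
  vmax0 <- max(v_all)
  km0 <- s_all[which.min(abs(v_all - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s),
                      data = data.frame(s = s_all, v = v_all),
                      start = list(vmax = vmax0, km = max(km0, 1e-3)),
                      lower = c(vmax = 0, km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(km = NA_real_, vmax = NA_real_, kcat = NA_real_,
                          se_km = NA_real_, se_vmax = NA_real_,
                          enzyme_nM = enzyme_nM, substrate = substrate,
                          rates = rate, nls = NULL, variant = variant,
                          converged = FALSE),
                     class = "mm_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  converged <- all(cf > 0)
  structure(list(km = unname(cf["km"]), vmax = unname(cf["vmax"]),
                 kcat = kcat_from_vmax(unname(cf["vmax"]), enzyme_nM),
                 se_km = unname(se["km"]), se_vmax = unname(se["vmax"]),
                 enzyme_nM = enzyme_nM, substrate = substrate, rates = rate,
                 nls = fit, variant = variant, converged = converged),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%s, %g nM enzyme)\n", x$variant, x$enzyme_nM))
  cat(sprintf("  Km   = %.3f +/- %.3f uM\n", x$km, x$se_km))
  cat(sprintf("  Vmax = %.4f +/- %.4f uM/min\n", x$vmax, x$se_vmax))
  cat(sprintf("  kcat = %.3f s^-1\n", x$kcat))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(km = object$km, vmax = object$vmax, kcat = object$kcat)
}

#' @export
summary.mm_fit <- function(object, ...) {
  data.frame(variant = object$variant, km_uM = object$km, km_se = object$se_km,
             vmax_uM_min = object$vmax, vmax_se = object$se_vmax,
             kcat_s = object$kcat, n_points = length(object$substrate))
}

#' @param object An \code{"mm_fit"}.
#' @param newdata Optional list/data.frame with a \code{substrate} element.
#' @param ... Unused.
#' @describeIn mm_fit Predicted rates at new substrate concentrations.
#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$substrate else newdata$substrate
  object$vmax * s / (object$km + s)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$rates - predict(object, list(substrate = object$substrate))
}

#' @param x An \code{"mm_fit"}.
#' @describeIn mm_fit Rates vs substrate with the fitted hyperbola.
#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$substrate, x$rates, xlab = "substrate (uM)",
                 ylab = "rate (uM/min)", ...)
  s <- seq(min(x$substrate), max(x$substrate), length.out = 200)
  graphics::lines(s, predict(x, list(substrate = s)), col = "firebrick")
  invisible(x)
}

#' Turnover number from Vmax
#'
#' Converts a maximal velocity in uM/min at a given enzyme concentration in
#' nM to a turnover number in s^-1:
#' \code{kcat = (vmax * 1000 / enzyme_nM) / 60}.
#'
#' @param vmax Maximal velocity (uM/min).
#' @param enzyme_nM Enzyme concentration (nM), > 0.
#' @return kcat in s^-1.
#' @examples
#' kcat_from_vmax(0.12, 1)  # 2.0
#' @export
kcat_from_vmax <- function(vmax, enzyme_nM) {
  if (enzyme_nM <= 0) stop("enzyme concentration must be > 0", call. = FALSE)
  (vmax * 1e3 / enzyme_nM) / 60
}

#' Percent reduction of a quantity relative to a reference
#'
#' @param ref Reference value, > 0.
#' @param test Test value.
#' @return \code{100 * (1 - test / ref)}.
#' @examples
#' percent_reduction(2.01, 1.5)  # ~25.4
#' @export
percent_reduction <- function(ref, test) {
  if (ref <= 0) stop("reference must be > 0", call. = FALSE)
  100 * (1 - test / ref)
}
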