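#' Construct a spectral envelope
#'
#' A spectral envelope is the m/z-intensity array recorded for one peptide /
#' charge / state / exchange-timepoint / replicate: the unit every fit in the
#' package consumes. Envelopes are centroided stick spectra, one point per
#' nominal isotopologue peak.
#'
#' @param mz Strictly increasing m/z values (Th), length >= 2.
#' @param intensity Non-negative intensities, same length; total must be > 0.
#' @param peptide An [hdx_peptide()] object.
#' @param state State label (e.g. \code{"apo"}, \code{"complex"},
#'   \code{"+cAMP"}).
#' @param t_ex Exchange time in minutes.
#' @param replicate Replicate index.
#' @return A \code{data.frame} of class \code{"spectral_envelope"} with columns
#'   \code{mz}, \code{intensity} and attributes \code{peptide}, \code{state},
#'   \code{t_ex}, \code{replicate}.
#' @export
spectral_envelope <- function(mz, intensity, peptide, state = "apo",
                              t_ex = NA_real_, replicate = 1L) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) < 2L) stop("an envelope needs at least 2 points", call. = FALSE)
  if (any(diff(mz) <= 0)) stop("mz must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (sum(intensity) <= 0) stop("total intensity must be > 0", call. = FALSE)
  if (!inherits(peptide, "hdx_peptide")) stop("peptide must be an hdx_peptide", call. = FALSE)
  structure(data.frame(mz = mz, intensity = intensity),
            peptide = peptide, state = state, t_ex = t_ex,
            replicate = as.integer(replicate),
            class = c("spectral_envelope", "data.frame"))
}

#' Theoretical deuterated envelope (forward model)
#'
#' Convolves a natural-abundance isotope pattern with a Binomial(n_ex, p)
#' distribution of incorporated deuterons (mass shift 1.00628 Da each) and
#' renders the result on the m/z axis for the given charge. This is the shared
#' forward model of the binomial fitters and the synthetic-data generator.
#'
#' Peaks are aggregated by nominal index (isotopologue surplus + deuteron
#' count) with abundance-weighted masses, so the envelope centroid shift over
#' the undeuterated pattern is exactly \code{n_ex * p * 1.00628} Da.
#'
#' @param pattern An [natural_isotope_pattern()] result.
#' @param n_ex Number of exchange-competent amides (binomial n), >= 0.
#' @param p Per-site deuteration fraction in \code{[0, 1]}.
#' @param charge Positive charge state for m/z rendering.
#' @param peptide Optional [hdx_peptide()] carried on the returned envelope;
#'   a bare descriptor is synthesised if omitted.
#' @param state,t_ex,replicate Metadata passed to [spectral_envelope()].
#' @return A \code{"spectral_envelope"}; total intensity equals 1 (relative
#'   abundance scale).
#' @examples
#' pat <- natural_isotope_pattern("ALIYGAPRAATVKAKTNVKL")
#' env <- deuterated_envelope(pat, n_ex = 17, p = 0.3, charge = 2)
#' @export
deuterated_envelope <- function(pattern, n_ex, p, charge = 1L, peptide = NULL,
                                state = "apo", t_ex = NA_real_, replicate = 1L) {
  stopifnot(inherits(pattern, "isotope_pattern"))
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  n_ex <- as.integer(n_ex)
  if (n_ex < 0L) stop("n_ex must be >= 0", call. = FALSE)
  d <- .deuteration_dist(pattern, n_ex, p)
  if (is.null(peptide)) {
    peptide <- structure(list(sequence = NA_character_, start = NA_integer_,
                              end = NA_integer_, charge = as.integer(charge),
                              n_exchangeable = n_ex),
                         class = "hdx_peptide")
  }
  mz <- (d$m + charge * hdx_constants$mass_proton) / charge
  spectral_envelope(mz, d$ab, peptide, state = state, t_ex = t_ex,
                    replicate = replicate)
}

# pattern (x) binomial deuteration as an indexed stick distribution
.deuteration_dist <- function(pattern, n_ex, p) {
  pat <- list(ab = pattern$abundances, m = pattern$masses)
  if (n_ex == 0L) return(pat)
  bin <- list(ab = stats::dbinom(0:n_ex, n_ex, p),
              m = (0:n_ex) * hdx_constants$mass_dh)
  d <- .dist_full_convolve(pat, bin)
  d
}

# like .dist_convolve but indices are positions in the mass vectors (masses
# need not start at 0) and zero-abundance interior peaks are kept so mixtures
# share one grid
.dist_full_convolve <- function(a, b) {
  na <- length(a$ab); nb <- length(b$ab)
  w <- outer(a$ab, b$ab)
  msum <- outer(a$m, b$m, "+")
  k <- outer(seq_len(na) - 1L, seq_len(nb) - 1L, "+")
  kmax <- na + nb - 2L
  ab <- numeric(kmax + 1L)
  mw <- numeric(kmax + 1L)
  for (kk in 0:kmax) {
    sel <- k == kk
    ab[kk + 1L] <- sum(w[sel])
    mw[kk + 1L] <- sum(w[sel] * msum[sel])
  }
  # zero-abundance peaks get the grid-extrapolated mass so mz stays increasing
  m <- ifelse(ab > 0, mw / pmax(ab, 1e-300),
              a$m[1] + b$m[1] + (0:kmax) * hdx_constants$index_spacing)
  m <- cummax(m)  # guard monotonicity where extrapolation meets data
  list(ab = ab, m = m)
}

#' Intensity-weighted centroid of an envelope
#'
#' Intensity-weighted mean m/z converted to the neutral-mass scale:
#' \code{(<m/z> - 1.00728) * charge}. The neutral scale makes centroids (and
#' hence uptake values) comparable across charge states.
#'
#' @param envelope A [spectral_envelope()].
#' @return Neutral-mass centroid in Da.
#' @examples
#' pep <- hdx_peptide("ALIYGAPRAATVKAKTNVKL", charge = 2)
#' env <- spectral_envelope(c(500, 501), c(1, 1), pep)
#' centroid(env)
#' @export
centroid <- function(envelope) {
  stopifnot(inherits(envelope, "spectral_envelope"))
  tot <- sum(envelope$intensity)
  if (tot <= 0) stop("zero total intensity", call. = FALSE)
  charge <- attr(envelope, "peptide")$charge
  mz_bar <- sum(envelope$mz * envelope$intensity) / tot
  (mz_bar - hdx_constants$mass_proton) * charge
}

#' @export
print.spectral_envelope <- function(x, ...) {
  pep <- attr(x, "peptide")
  cat(sprintf("<spectral_envelope> %s (+%d) state=%s t_ex=%s min rep=%d, %d points\n",
              ifelse(is.na(pep$sequence), "?", pep$sequence), pep$charge,
              attr(x, "state"), format(attr(x, "t_ex")), attr(x, "replicate"),
              nrow(x)))
  invisible(x)
}

#' @describeIn spectral_envelope Plot an envelope as a stick spectrum.
#' @param x A \code{"spectral_envelope"}.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.spectral_envelope <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "h", xlab = "m/z (Th)",
                 ylab = "intensity", ...)
  invisible(x)
}

#' Flatten envelopes to the long exchange table
#'
#' One row per spectral point: \code{peptide_id, sequence, start, end, charge,
#' state, t_ex_min, replicate, mz, intensity}. The inverse of
#' [envelopes_from_table()].
#'
#' @param envelopes A list of [spectral_envelope()] objects.
#' @return A \code{data.frame} in the documented long dialect.
#' @export
envelope_table <- function(envelopes) {
  if (inherits(envelopes, "spectral_envelope")) envelopes <- list(envelopes)
  do.call(rbind, lapply(envelopes, function(e) {
    pep <- attr(e, "peptide")
    data.frame(peptide_id = sprintf("%s-%s", pep$start, pep$end),
               sequence = pep$sequence, start = pep$start, end = pep$end,
               charge = pep$charge, state = attr(e, "state"),
               t_ex_min = attr(e, "t_ex"), replicate = attr(e, "replicate"),
               mz = e$mz, intensity = e$intensity)
  }))
}

#' Rebuild envelopes from the long exchange table
#'
#' @param tab A \code{data.frame} as produced by [envelope_table()].
#' @return A list of [spectral_envelope()] objects, one per
#'   (peptide, charge, state, t_ex, replicate) group.
#' @export
envelopes_from_table <- function(tab) {
  key <- interaction(tab$peptide_id, tab$charge, tab$state, tab$t_ex_min,
                     tab$replicate, drop = TRUE)
  lapply(split(tab, key), function(g) {
    g <- g[order(g$mz), ]
    pep <- hdx_peptide(g$sequence[1], start = g$start[1], end = g$end[1],
                       charge = g$charge[1])
    spectral_envelope(g$mz, g$intensity, pep, state = g$state[1],
                      t_ex = g$t_ex_min[1], replicate = g$replicate[1])
  })
}
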