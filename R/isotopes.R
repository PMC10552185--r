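# Natural-abundance isotope pattern from elemental composition.
#
# Distributions are kept as paired vectors indexed by neutron surplus k
# (0, 1, 2, ...): `ab[k+1]` is the probability of k extra neutrons and
# `m[k+1]` the abundance-weighted mean mass of that nominal isotopologue.
# Convolving two such distributions sums indices, multiplies abundances and
# adds masses, keeping the weighted mean per nominal peak; this reproduces a
# full enumeration over isotopologues up to merging of same-k fine structure,
# which is far below 1e-6 Da at peptide size.

.dist_convolve <- function(a, b) {
  w <- outer(a$ab, b$ab)
  msum <- outer(a$m, b$m, "+")
  k <- outer(seq_along(a$ab) - 1L, seq_along(b$ab) - 1L, "+")
  kmax <- max(k)
  ab <- numeric(kmax + 1L)
  mw <- numeric(kmax + 1L)
  for (kk in 0:kmax) {
    sel <- k == kk
    ab[kk + 1L] <- sum(w[sel])
    mw[kk + 1L] <- sum(w[sel] * msum[sel])
  }
  keep <- ab > 1e-15
  last <- max(which(keep))
  ab <- ab[seq_len(last)]
  mw <- mw[seq_len(last)]
  list(ab = ab, m = ifelse(ab > 0, mw / pmax(ab, 1e-300), 0))
}

.dist_power <- function(d, n) {
  # exponentiation by squaring
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else .dist_convolve(result, base)
    }
    n <- n %/% 2
    if (n > 0) base <- .dist_convolve(base, base)
  }
  if (is.null(result)) list(ab = 1, m = 0) else result
}

.element_dist <- function(symbol) {
  iso <- .element_isotopes[[symbol]]
  kmax <- max(iso$dn)
  ab <- numeric(kmax + 1L)
  m <- numeric(kmax + 1L)
  ab[iso$dn + 1L] <- iso$abundance
  m[iso$dn + 1L] <- iso$mass
  list(ab = ab, m = m)
}

#' Natural-abundance isotope pattern of a peptide
#'
#' Computes the neutral-mass isotope distribution of an undeuterated peptide
#' from its elemental composition (residue formulas plus one water) by
#' iterative polynomial convolution of the per-element isotope distributions.
#' Each returned peak is one nominal isotopologue (0, 1, 2, ... surplus
#' neutrons) carrying the abundance-weighted exact mass of its fine structure.
#' The pattern is truncated once the cumulative abundance reaches 0.9999 and
#' renormalised to sum to 1.
#'
#' @param sequence Amino-acid sequence (1-letter codes, standard 20 residues).
#' @return An object of class \code{"isotope_pattern"}: list with
#'   \code{masses} (neutral Da, first element the monoisotopic mass, increasing)
#'   and \code{abundances} (non-negative, summing to 1).
#' @examples
#' pat <- natural_isotope_pattern("ALIYGAPRAATVKAKTNVKL")
#' pat$abundances[2] / pat$abundances[1]  # M+1 / M ratio
#' @export
natural_isotope_pattern <- function(sequence) {
  counts <- .peptide_formula(sequence)
  d <- NULL
  for (el in names(counts)) {
    if (counts[[el]] == 0) next
    pe <- .dist_power(.element_dist(el), counts[[el]])
    d <- if (is.null(d)) pe else .dist_convolve(d, pe)
  }
  cum <- cumsum(d$ab)
  last <- which(cum >= 0.9999)[1]
  if (is.na(last)) last <- length(d$ab)
  ab <- d$ab[seq_len(last)]
  structure(list(masses = d$m[seq_len(last)], abundances = ab / sum(ab)),
            class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(sprintf("<isotope_pattern> %d peaks, monoisotopic %.5f Da\n",
              length(x$masses), x$masses[1]))
  print(data.frame(mass = round(x$masses, 5),
                   abundance = signif(x$abundances, 4)), row.names = FALSE)
  invisible(x)
}
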