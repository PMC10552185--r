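# Seeded synthetic-data generator: spectra, uptake tables, assay data.
# Stands in for deposited raw measurements; every output is reproducible
# under a fixed seed and feeds the same forward model the fitters use.

# run expr with a temporarily-set RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Noise model for synthetic spectra
#'
#' Multiplicative Gaussian intensity noise plus an additive Gaussian
#' baseline: \code{y = signal * (1 + N(0, cv^2)) + N(0, baseline_sd^2)},
#' clamped at zero.
#'
#' @param intensity_cv Coefficient of variation of the multiplicative
#'   component (default 0.01).
#' @param baseline_sd Absolute SD of the additive baseline component, on the
#'   intensity scale of the envelope (default 0).
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#' @return A named list.
#' @export
noise_model <- function(intensity_cv = 0.01, baseline_sd = 0, seed = NULL) {
  stopifnot(intensity_cv >= 0, baseline_sd >= 0)
  list(intensity_cv = intensity_cv, baseline_sd = baseline_sd, seed = seed)
}

#' Simulate a spectral envelope from a population mixture
#'
#' Renders the forward-model mixture of deuterated envelopes for a set of
#' co-existing populations (e.g. a ligand-bound low-exchanging and a
#' ligand-free high-exchanging conformation), adds noise per
#' [noise_model()], and pads the envelope with signal-free flank points used
#' downstream for baseline-noise estimation.
#'
#' @param peptide An [hdx_peptide()].
#' @param populations \code{data.frame} with columns \code{fraction}
#'   (summing to 1 within 1e-6) and either \code{uptake} (mean uptake in Da)
#'   or \code{p} (per-site deuteration fraction).
#' @param noise A [noise_model()].
#' @param state,t_ex,replicate Envelope metadata.
#' @param total_intensity Total ion intensity of the noiseless envelope
#'   (default 1e6, counts-like scale).
#' @param pad Number of zero-signal flank points added on each side
#'   (default 5).
#' @return A [spectral_envelope()].
#' @examples
#' pep <- hdx_peptide("ALIYGAPRAATVKAKTNVKL", start = 202, end = 221, charge = 2)
#' env <- simulate_envelope(pep,
#'   data.frame(fraction = c(0.856, 0.144), uptake = c(2.8, 7.79)),
#'   noise = noise_model(0.01, seed = 7), t_ex = 10)
#' @export
simulate_envelope <- function(peptide, populations, noise = noise_model(),
                              state = "complex", t_ex = NA_real_,
                              replicate = 1L, total_intensity = 1e6, pad = 5L) {
  stopifnot(inherits(peptide, "hdx_peptide"))
  if (abs(sum(populations$fraction) - 1) > 1e-6) {
    stop("population fractions must sum to 1", call. = FALSE)
  }
  n_ex <- peptide$n_exchangeable
  p <- if ("p" %in% names(populations)) populations$p else {
    populations$uptake / (n_ex * hdx_constants$mass_dh)
  }
  if (any(p < 0 | p > 1)) stop("per-site deuteration fractions outside [0, 1]",
                               call. = FALSE)
  pattern <- natural_isotope_pattern(peptide$sequence)
  dists <- lapply(p, function(pp) .deuteration_dist(pattern, n_ex, pp))
  w <- populations$fraction
  ab <- Reduce(`+`, Map(function(d, wi) wi * d$ab, dists, w))
  mnum <- Reduce(`+`, Map(function(d, wi) wi * d$ab * d$m, dists, w))
  k <- seq_along(ab) - 1L
  mono <- pattern$masses[1]
  m <- ifelse(ab > 0, mnum / pmax(ab, 1e-300),
              mono + k * hdx_constants$index_spacing)
  m <- cummax(m)
  if (pad > 0) {
    left <- mono - (pad:1) * hdx_constants$index_spacing
    right <- m[length(m)] + (1:pad) * hdx_constants$index_spacing
    m <- c(left, m, right)
    ab <- c(numeric(pad), ab, numeric(pad))
  }
  y <- ab * total_intensity
  y <- .with_seed(noise$seed, {
    yy <- y * (1 + stats::rnorm(length(y), 0, noise$intensity_cv))
    yy + stats::rnorm(length(y), 0, noise$baseline_sd)
  })
  y <- pmax(y, 0)
  mz <- (m + peptide$charge * hdx_constants$mass_proton) / peptide$charge
  spectral_envelope(mz, y, peptide, state = state, t_ex = t_ex,
                    replicate = replicate)
}

#' Simulate a replicate time series of (possibly bimodal) envelopes
#'
#' Applies [simulate_envelope()] across an exchange-time schedule with
#' replicates. Each schedule row gives the bound (low-exchanging) population
#' fraction and the two population uptakes at one timepoint; rows with
#' \code{frac_low} 1 or 0 generate unimodal envelopes.
#'
#' @param peptide An [hdx_peptide()].
#' @param schedule \code{data.frame} with columns \code{t_ex_min},
#'   \code{frac_low}, \code{uptake_low}, \code{uptake_high}.
#' @param n_replicates Replicates per timepoint (default 3).
#' @param noise A [noise_model()] (its seed, combined with the replicate and
#'   timepoint indices, seeds each envelope).
#' @param state State label.
#' @param ... Passed to [simulate_envelope()].
#' @return List of [spectral_envelope()] objects, timepoint-major.
#' @export
simulate_bimodal_series <- function(peptide, schedule, n_replicates = 3L,
                                    noise = noise_model(seed = 1L),
                                    state = "complex", ...) {
  stopifnot(all(schedule$frac_low >= 0), all(schedule$frac_low <= 1))
  base_seed <- if (is.null(noise$seed)) 0L else noise$seed
  out <- list()
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    pops <- data.frame(fraction = c(row$frac_low, 1 - row$frac_low),
                       uptake = c(row$uptake_low, row$uptake_high))
    pops <- pops[pops$fraction > 0, , drop = FALSE]
    for (r in seq_len(n_replicates)) {
      nm <- noise
      nm$seed <- (base_seed + 1000L * i + r) %% .Machine$integer.max
      out[[length(out) + 1L]] <- simulate_envelope(
        peptide, pops, noise = nm, state = state, t_ex = row$t_ex_min,
        replicate = r, ...)
    }
  }
  out
}

#' Simulate two-state replicate uptake tables with injected differences
#'
#' Generates replicate deuterium-uptake values for a peptide set in a test
#' state and a reference state, where the test state's true uptake is the
#' reference uptake plus an injected per-peptide difference, and replicate
#' scatter is Gaussian. Returns both tables in the [uptake_table()] dialect.
#'
#' @param peptides List of [hdx_peptide()] objects.
#' @param true_deltas Numeric vector (one per peptide) of injected
#'   state-minus-reference differences in Da, or a matrix
#'   \code{length(peptides) x length(t_ex)}.
#' @param base_uptake Reference-state true uptake in Da (scalar or per
#'   peptide; default 2).
#' @param replicate_sd Replicate SD in Da (default 0.05).
#' @param t_ex Exchange timepoints in minutes (default \code{c(1, 10, 30)}).
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Integer seed.
#' @param states Labels for the two states.
#' @return Named list \code{state}, \code{reference} of uptake tables.
#' @export
simulate_two_state_uptake <- function(peptides, true_deltas, base_uptake = 2,
                                      replicate_sd = 0.05,
                                      t_ex = c(1, 10, 30), n_replicates = 3L,
                                      seed = 1L,
                                      states = c("state", "reference")) {
  np <- length(peptides)
  deltas <- if (is.matrix(true_deltas)) true_deltas else {
    matrix(rep(true_deltas, length.out = np), nrow = np, ncol = length(t_ex))
  }
  base <- rep(base_uptake, length.out = np)
  .with_seed(seed, {
    rows <- list()
    for (i in seq_len(np)) {
      pep <- peptides[[i]]
      for (j in seq_along(t_ex)) {
        for (st in 1:2) {
          mu <- base[i] + if (st == 1) deltas[i, j] else 0
          vals <- pmax(stats::rnorm(n_replicates, mu, replicate_sd), 0)
          s <- replicate_stats(vals)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide_id = sprintf("%s-%s", pep$start, pep$end),
            sequence = pep$sequence, start = pep$start, end = pep$end,
            state = states[st], t_ex_min = t_ex[j],
            uptake_mean_Da = unname(s["mean"]),
            uptake_sd_Da = unname(s["sd"]), n = n_replicates)
        }
      }
    }
    tab <- do.call(rbind, rows)
    list(state = tab[tab$state == states[1], ],
         reference = tab[tab$state == states[2], ])
  })
}

#' Simulate a linked phosphodiesterase initial-rate assay
#'
#' Triplicate Michaelis-Menten rates over a substrate grid with
#' multiplicative Gaussian noise:
#' \code{v = Vmax S / (Km + S) * (1 + N(0, cv^2))}. Supply either
#' \code{vmax} (uM/min) or \code{kcat} (s^-1, converted via the enzyme
#' concentration).
#'
#' @param km True Michaelis constant (uM).
#' @param vmax True maximal velocity (uM/min); derived from \code{kcat} if
#'   missing.
#' @param kcat True turnover number (s^-1), alternative to \code{vmax}.
#' @param enzyme_nM Enzyme concentration (nM), default 1.
#' @param substrate Substrate grid (uM), default
#'   \code{c(0.25, 0.5, 1, 2, 5, 10)} spanning the expected Km.
#' @param cv Multiplicative noise CV (default 0.05).
#' @param n_replicates Replicates per level (default 3).
#' @param seed Integer seed.
#' @param variant Variant label.
#' @return \code{data.frame} with columns \code{variant},
#'   \code{substrate_uM}, \code{rate_uM_per_min}, \code{replicate}.
#' @export
simulate_mm_assay <- function(km, vmax = NULL, kcat = NULL, enzyme_nM = 1,
                              substrate = c(0.25, 0.5, 1, 2, 5, 10),
                              cv = 0.05, n_replicates = 3L, seed = 1L,
                              variant = "WT") {
  stopifnot(km > 0, all(substrate > 0))
  if (is.null(vmax)) {
    if (is.null(kcat)) stop("supply vmax or kcat", call. = FALSE)
    vmax <- kcat * 60 * enzyme_nM / 1e3
  }
  .with_seed(seed, {
    s <- rep(substrate, each = n_replicates)
    v_true <- vmax * s / (km + s)
    v <- v_true * (1 + stats::rnorm(length(s), 0, cv))
    data.frame(variant = variant, substrate_uM = s, rate_uM_per_min = v,
               replicate = rep(seq_len(n_replicates), times = length(substrate)))
  })
}

#' Reporter peptides of the regulatory-subunit cAMP-binding sites
#'
#' The peptic reporter peptides used throughout the package examples and
#' tests: the phosphate-binding-cassette peptides of the two tandem
#' cyclic-nucleotide-binding (CNB) domains with their published sequences,
#' and the CNB:B interfacial peptide 271-290, whose sequence is not printed
#' in the source data and is therefore a synthetic placeholder of the right
#' length (marked \code{synthetic = TRUE}).
#'
#' @param charge Charge state assigned to every peptide (default 2).
#' @return Named list of [hdx_peptide()] objects.
#' @export
reporter_peptides <- function(charge = 2L) {
  peps <- list(
    "202-221" = hdx_peptide("ALIYGAPRAATVKAKTNVKL", 202, 221, charge),
    "206-221" = hdx_peptide("GAPRAATVKAKTNVKL", 206, 221, charge),
    "329-336" = hdx_peptide("MNRPRAAT", 329, 336, charge),
    "330-336" = hdx_peptide("NRPRAAT", 330, 336, charge),
    # sequence not published; synthetic 20-mer stand-in
    "271-290" = hdx_peptide("GELALMYNTPRAATIVATSE", 271, 290, charge))
  attr(peps[["271-290"]], "synthetic") <- TRUE
  peps
}
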