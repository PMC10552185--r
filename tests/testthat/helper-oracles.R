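# Independent brute-force oracles, kept deliberately naive and separate from
# the package's convolution code paths.

# Element isotope tables duplicated from first principles (CODATA/IUPAC
# values) so the oracle does not read package internals.
oracle_isotopes <- list(
  C = list(mass = c(12.0000000, 13.0033548), ab = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503, 2.01410178), ab = c(0.999885, 0.000115)),
  N = list(mass = c(14.00307401, 15.00010890), ab = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491462, 16.99913176, 17.99915961),
           ab = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207117, 32.97145891, 33.96786701, 35.96708076),
           ab = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Exhaustive enumeration of isotopologues of a molecular formula: multinomial
# expansion per element, cartesian product across elements, aggregated by
# nominal neutron surplus. Returns data.frame(k, mass, ab): per-nominal-peak
# abundance and abundance-weighted mean mass.
oracle_pattern <- function(formula) {
  per_element <- lapply(names(formula), function(el) {
    n <- formula[[el]]
    if (n == 0) return(data.frame(k = 0L, mass = 0, ab = 1))
    iso <- oracle_isotopes[[el]]
    ni <- length(iso$mass)
    # all compositions of n atoms over ni isotopes
    comps <- expand.grid(rep(list(0:n), ni))
    comps <- comps[rowSums(comps) == n, , drop = FALSE]
    ab <- apply(comps, 1, function(cnt) {
      exp(lgamma(n + 1) - sum(lgamma(cnt + 1)) + sum(cnt * log(iso$ab)))
    })
    mass <- as.matrix(comps) %*% iso$mass
    k <- as.matrix(comps) %*% (round(iso$mass) - round(iso$mass[1]))
    d <- data.frame(k = as.integer(k), mass = as.numeric(mass), ab = ab)
    d[d$ab > 1e-16, ]  # prune negligible isotopologues to bound the product
  })
  combined <- Reduce(function(a, b) {
    out <- merge(a, b, by = NULL)  # cartesian product
    out <- data.frame(k = out$k.x + out$k.y, mass = out$mass.x + out$mass.y,
                      ab = out$ab.x * out$ab.y)
    out[out$ab > 1e-16, ]
  }, per_element)
  combined <- combined[combined$ab > 1e-18, ]
  agg_ab <- tapply(combined$ab, combined$k, sum)
  agg_m <- tapply(combined$ab * combined$mass, combined$k, sum) / agg_ab
  data.frame(k = as.integer(names(agg_ab)), mass = as.numeric(agg_m),
             ab = as.numeric(agg_ab))
}

# CHNOS formula of a peptide assembled from free-amino-acid compositions
# minus waters (independent bookkeeping from the package's residue table)
oracle_peptide_formula <- function(sequence) {
  aa_formulas <- list(  # free amino acids
    A = c(C = 3, H = 7, N = 1, O = 2, S = 0), R = c(C = 6, H = 14, N = 4, O = 2, S = 0),
    N = c(C = 4, H = 8, N = 2, O = 3, S = 0), D = c(C = 4, H = 7, N = 1, O = 4, S = 0),
    C = c(C = 3, H = 7, N = 1, O = 2, S = 1), Q = c(C = 5, H = 10, N = 2, O = 3, S = 0),
    E = c(C = 5, H = 9, N = 1, O = 4, S = 0), G = c(C = 2, H = 5, N = 1, O = 2, S = 0),
    H = c(C = 6, H = 9, N = 3, O = 2, S = 0), I = c(C = 6, H = 13, N = 1, O = 2, S = 0),
    L = c(C = 6, H = 13, N = 1, O = 2, S = 0), K = c(C = 6, H = 14, N = 2, O = 2, S = 0),
    M = c(C = 5, H = 11, N = 1, O = 2, S = 1), F = c(C = 9, H = 11, N = 1, O = 2, S = 0),
    P = c(C = 5, H = 9, N = 1, O = 2, S = 0), S = c(C = 3, H = 7, N = 1, O = 3, S = 0),
    T = c(C = 4, H = 9, N = 1, O = 3, S = 0), W = c(C = 11, H = 12, N = 2, O = 2, S = 0),
    Y = c(C = 9, H = 11, N = 1, O = 3, S = 0), V = c(C = 5, H = 11, N = 1, O = 2, S = 0))
  aa <- strsplit(sequence, "")[[1]]
  total <- Reduce(`+`, aa_formulas[aa])
  n_bonds <- length(aa) - 1
  total - n_bonds * c(C = 0, H = 2, N = 0, O = 1, S = 0)
}

# Exhaustive enumeration of a deuterated envelope for tiny problems:
# every (isotopologue peak j, deuteron count d) outcome listed explicitly.
oracle_deuterated <- function(pattern_ab, pattern_m, n_ex, p, mass_dh = 1.00628) {
  grid <- expand.grid(j = seq_along(pattern_ab), d = 0:n_ex)
  ab <- pattern_ab[grid$j] * choose(n_ex, grid$d) * p^grid$d * (1 - p)^(n_ex - grid$d)
  mass <- pattern_m[grid$j] + grid$d * mass_dh
  k <- (grid$j - 1L) + grid$d
  agg_ab <- tapply(ab, k, sum)
  agg_m <- tapply(ab * mass, k, sum) / agg_ab
  data.frame(k = as.integer(names(agg_ab)), mass = as.numeric(agg_m),
             ab = as.numeric(agg_ab))
}

# Dense grid-search least squares of a single binomial against observed
# intensities given a basis generator (independent of the package optimiser)
oracle_single_grid <- function(y, basis_fun, p_grid = seq(0.001, 0.999, by = 0.001)) {
  rss <- vapply(p_grid, function(p) {
    f <- basis_fun(p)
    a <- sum(y * f) / sum(f * f)
    sum((y - a * f)^2)
  }, numeric(1))
  list(p = p_grid[which.min(rss)], rss = min(rss))
}

table1_peptide <- function(charge = 2L) {
  hdx_peptide("ALIYGAPRAATVKAKTNVKL", start = 202, end = 221, charge = charge)
}
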