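# Forward model: isotope patterns, exchangeable-amide counting, deuteration
# convolution and centroids.

test_that("natural isotope pattern matches brute-force enumeration", {
  for (seq in c("G", "GAS", "MKT")) {
    pat <- natural_isotope_pattern(seq)
    orc <- oracle_pattern(as.list(oracle_peptide_formula(seq)))
    n <- min(length(pat$abundances), nrow(orc))
    expect_equal(pat$abundances[1:n],
                 (orc$ab / sum(orc$ab[1:n]))[1:n], tolerance = 2e-4)
    expect_equal(pat$masses[1:n], orc$mass[1:n], tolerance = 1e-6)
  }
})

test_that("glycine M+1/M abundance ratio is ~0.027", {
  pat <- natural_isotope_pattern("G")
  orc <- oracle_pattern(as.list(oracle_peptide_formula("G")))
  expect_equal(pat$abundances[2] / pat$abundances[1], orc$ab[2] / orc$ab[1],
               tolerance = 1e-9)
  expect_equal(pat$abundances[2] / pat$abundances[1], 0.027, tolerance = 0.02)
})

test_that("pattern abundances are a normalised distribution", {
  for (seq in c("G", "ALIYGAPRAATVKAKTNVKL", "WWCMSH")) {
    pat <- natural_isotope_pattern(seq)
    expect_equal(sum(pat$abundances), 1, tolerance = 1e-9)
    expect_true(all(pat$abundances >= 0))
    expect_true(all(diff(pat$masses) > 0))
  }
})

test_that("reporter peptide centroid offset agrees with the enumeration oracle", {
  seq <- "ALIYGAPRAATVKAKTNVKL"
  pat <- natural_isotope_pattern(seq)
  orc <- oracle_pattern(as.list(oracle_peptide_formula(seq)))
  cent_pkg <- sum(pat$masses * pat$abundances) - pat$masses[1]
  last <- which(cumsum(orc$ab) >= 0.9999)[1]  # same truncation rule
  orc <- orc[seq_len(last), ]
  cent_orc <- sum(orc$mass * orc$ab) / sum(orc$ab) - orc$mass[1]
  expect_equal(cent_pkg, cent_orc, tolerance = 1e-6)
})

test_that("unknown residues are rejected with a named error", {
  expect_error(natural_isotope_pattern("AXZ"), "unknown_residue")
  expect_error(hdx_peptide("AB"), "unknown_residue")
})

test_that("exchangeable amide counting follows the len-2-internal-proline rule", {
  expect_identical(count_exchangeable("ALIYGAPRAATVKAKTNVKL"), 17L)
  expect_identical(count_exchangeable("AA"), 0L)
  # prolines in the excluded N-terminal pair are not double-counted
  expect_identical(count_exchangeable("APPA"), 1L)
  expect_identical(count_exchangeable("APAP"), 1L)
  expect_identical(count_exchangeable("PPAAA"), 3L)  # leading prolines exempt
  expect_error(count_exchangeable("A"), "length")
})

test_that("deuteration convolution has binomial-mean centroid shifts", {
  pat <- natural_isotope_pattern("ALIYGAPRAATVKAKTNVKL")
  und <- deuterated_envelope(pat, 17, 0, charge = 2)
  # p = 0: identical to the natural pattern (plus trailing zero-intensity grid)
  expect_equal(und$intensity[seq_along(pat$abundances)], pat$abundances)
  expect_equal(sum(und$intensity), 1, tolerance = 1e-9)
  # degenerate p = 1: full shift
  full <- deuterated_envelope(pat, 10, 1, charge = 2)
  expect_equal(centroid(full) - centroid(und), 10 * 1.00628, tolerance = 1e-9)
  # binomial mean n * p
  part <- deuterated_envelope(pat, 18, 0.3, charge = 2)
  expect_equal(centroid(part) - centroid(und), 18 * 0.3 * 1.00628,
               tolerance = 1e-9)
})

test_that("deuteration conserves total intensity", {
  pat <- natural_isotope_pattern("GASMKT")
  for (p in c(0.1, 0.5, 0.93)) {
    env <- deuterated_envelope(pat, 4, p)
    expect_equal(sum(env$intensity), 1, tolerance = 1e-9)
  }
})

test_that("small-n deuterated envelopes equal exhaustive enumeration", {
  pat <- natural_isotope_pattern("GAS")
  pat3 <- list(masses = pat$masses[1:3],
               abundances = pat$abundances[1:3] / sum(pat$abundances[1:3]))
  class(pat3) <- "isotope_pattern"
  for (n_ex in 1:5) {
    for (p in c(0.2, 0.5, 0.8)) {
      env <- deuterated_envelope(pat3, n_ex, p, charge = 1)
      orc <- oracle_deuterated(pat3$abundances, pat3$masses, n_ex, p)
      expect_equal(env$intensity, orc$ab, tolerance = 1e-12)
      neutral <- (env$mz - 1.00728) * 1
      expect_equal(neutral, orc$mass, tolerance = 1e-9)
    }
  }
})

test_that("centroid computes the intensity-weighted neutral mass", {
  pep2 <- hdx_peptide("AG", charge = 2)
  env <- spectral_envelope(c(500.0, 501.0), c(1, 1e-12), pep2)
  expect_equal(centroid(env), (500 - 1.00728) * 2, tolerance = 1e-3)
  pep1 <- hdx_peptide("AG", charge = 1)
  sym <- spectral_envelope(c(599, 600, 601), c(1, 3, 1), pep1)
  expect_equal(centroid(sym), 600 - 1.00728, tolerance = 1e-9)
  two <- spectral_envelope(c(100, 101), c(1, 3), pep1)
  expect_equal(centroid(two), (100.75 - 1.00728) * 1, tolerance = 1e-9)
})

test_that("centroid is linear under envelope mixing", {
  pep <- table1_peptide()
  pat <- natural_isotope_pattern(pep$sequence)
  e1 <- deuterated_envelope(pat, 17, 0.15, 2, peptide = pep)
  e2 <- deuterated_envelope(pat, 17, 0.55, 2, peptide = pep)
  for (w in c(0.1, 0.5, 0.856)) {
    # mix on a shared grid: combine intensities, weighted-mean masses
    ab <- w * e1$intensity + (1 - w) * e2$intensity
    mz <- (w * e1$intensity * e1$mz + (1 - w) * e2$intensity * e2$mz) /
      pmax(ab, 1e-300)
    ok <- ab > 0
    mixed <- spectral_envelope(mz[ok], ab[ok], pep)
    expect_equal(centroid(mixed),
                 w * centroid(e1) + (1 - w) * centroid(e2), tolerance = 1e-9)
  }
})

test_that("centroid increases strictly with deuteration fraction", {
  pat <- natural_isotope_pattern("ALIYGAPRAATVKAKTNVKL")
  ps <- seq(0.05, 0.95, by = 0.1)
  cents <- vapply(ps, function(p) centroid(deuterated_envelope(pat, 17, p, 2)),
                  numeric(1))
  expect_true(all(diff(cents) > 0))
})

test_that("envelope long-table round-trips", {
  pep <- table1_peptide()
  env <- simulate_envelope(pep, data.frame(fraction = 1, uptake = 3),
                           noise = noise_model(0.01, 10, seed = 11), t_ex = 10)
  tab <- envelope_table(env)
  back <- envelopes_from_table(tab)
  expect_length(back, 1)
  expect_equal(back[[1]]$mz, env$mz)
  expect_equal(back[[1]]$intensity, env$intensity)
  expect_equal(attr(back[[1]], "t_ex"), 10)
})

test_that("envelope validation rejects malformed inputs", {
  pep <- hdx_peptide("AG")
  expect_error(spectral_envelope(c(1, 1), c(1, 1), pep), "increasing")
  expect_error(spectral_envelope(c(1, 2), c(0, 0), pep), "total intensity")
  expect_error(spectral_envelope(c(1, 2), c(-1, 2), pep), "non-negative")
  expect_error(spectral_envelope(1, 1, pep), "2 points")
})
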