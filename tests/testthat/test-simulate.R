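# Synthetic-data generator: determinism, forward-model fidelity, scenarios.

test_that("same seed gives bit-identical envelopes", {
  pep <- table1_peptide()
  pops <- data.frame(fraction = c(0.65, 0.35), uptake = c(3.32, 8.65))
  a <- simulate_envelope(pep, pops, noise_model(0.02, 50, seed = 123))
  b <- simulate_envelope(pep, pops, noise_model(0.02, 50, seed = 123))
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
  c <- simulate_envelope(pep, pops, noise_model(0.02, 50, seed = 124))
  expect_false(identical(b$intensity, c$intensity))
})

test_that("seeding does not disturb the global RNG stream", {
  set.seed(1); before <- runif(5)
  set.seed(1); invisible(runif(2))
  invisible(simulate_envelope(table1_peptide(),
                              data.frame(fraction = 1, uptake = 3),
                              noise_model(0.01, 10, seed = 55)))
  after <- runif(3)
  expect_identical(before[3:5], after)
})

test_that("population fractions must sum to one", {
  expect_error(simulate_envelope(table1_peptide(),
                                 data.frame(fraction = c(0.6, 0.3),
                                            uptake = c(2, 7))),
               "sum to 1")
})

test_that("zero-noise single population reproduces the forward model", {
  pep <- table1_peptide()
  pat <- natural_isotope_pattern(pep$sequence)
  sim <- simulate_envelope(pep, data.frame(fraction = 1, p = 0.3),
                           noise = noise_model(0, 0), total_intensity = 1)
  ref <- deuterated_envelope(pat, 17, 0.3, 2, peptide = pep)
  core <- sim$intensity[sim$intensity > 0]
  expect_equal(core, ref$intensity[ref$intensity > 0], tolerance = 1e-12)
})

test_that("mixture centroid shift equals the fraction-weighted uptake", {
  pep <- table1_peptide()
  pat <- natural_isotope_pattern(pep$sequence)
  und <- deuterated_envelope(pat, 17, 0, 2, peptide = pep)
  env <- simulate_envelope(pep, data.frame(fraction = c(0.856, 0.144),
                                           uptake = c(2.8, 7.79)),
                           noise = noise_model(0, 0), t_ex = 10)
  expect_equal(centroid(env) - centroid(und),
               0.856 * 2.8 + 0.144 * 7.79, tolerance = 1e-3)
})

test_that("a bound-population schedule produces the expected spectral classes", {
  pep <- table1_peptide()
  sched <- data.frame(t_ex_min = c(1, 10, 30),
                      frac_low = c(1, 0.5, 0),
                      uptake_low = c(2.5, 2.8, 3.3),
                      uptake_high = c(7.5, 7.8, 8.6))
  envs <- simulate_bimodal_series(pep, sched, n_replicates = 1,
                                  noise = noise_model(0.01, 20, seed = 31))
  rep <- bimodal_report(envs, intensity_cv = 0.01)
  expect_identical(rep$classification[rep$t_ex_min == 1], "unimodal")
  expect_identical(rep$classification[rep$t_ex_min == 10], "bimodal")
  expect_identical(rep$classification[rep$t_ex_min == 30], "unimodal")
  # the late unimodal envelope sits at the high-exchanging centroid
  pat <- natural_isotope_pattern(pep$sequence)
  und <- deuterated_envelope(pat, 17, 0, 2, peptide = pep)
  late <- envs[[which(rep$t_ex_min == 30)]]
  expect_equal(deuterium_uptake(late, und), 8.6, tolerance = 0.05)
})

test_that("assay simulation is exact at zero CV and saturates at Vmax", {
  tab <- simulate_mm_assay(1.0, vmax = 0.1, cv = 0, seed = 1,
                           substrate = c(0.25, 1, 5, 1000))
  expect_equal(tab$rate_uM_per_min[tab$substrate_uM == 1], rep(0.05, 3))
  expect_equal(tab$rate_uM_per_min[tab$substrate_uM == 1000],
               rep(0.1, 3), tolerance = 1e-3)
  t1 <- simulate_mm_assay(1.13, vmax = 0.12, seed = 9)
  t2 <- simulate_mm_assay(1.13, vmax = 0.12, seed = 9)
  expect_identical(t1, t2)
})

test_that("two-state generator is reproducible and respects zero deltas", {
  peps <- reporter_peptides()["202-221"]
  a <- simulate_two_state_uptake(peps, 0, replicate_sd = 0.05, seed = 13)
  b <- simulate_two_state_uptake(peps, 0, replicate_sd = 0.05, seed = 13)
  expect_identical(a, b)
  d <- difference_records(a$state, a$reference)
  expect_true(all(abs(d$delta_Da) < 0.3))
})

test_that("reporter peptide set carries published sequences and spans", {
  peps <- reporter_peptides()
  expect_identical(peps[["202-221"]]$sequence, "ALIYGAPRAATVKAKTNVKL")
  expect_identical(peps[["206-221"]]$sequence, "GAPRAATVKAKTNVKL")
  expect_identical(peps[["329-336"]]$sequence, "MNRPRAAT")
  expect_identical(peps[["330-336"]]$sequence, "NRPRAAT")
  expect_true(isTRUE(attr(peps[["271-290"]], "synthetic")))
  for (p in peps) expect_identical(nchar(p$sequence), p$end - p$start + 1L)
})
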