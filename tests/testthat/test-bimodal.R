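# Single/double binomial fitting, F-test selection, classification and
# population fractions.

table1_envelope <- function(frac_low, uptake_low, uptake_high, noise, t_ex) {
  simulate_envelope(table1_peptide(),
                    data.frame(fraction = c(frac_low, 1 - frac_low),
                               uptake = c(uptake_low, uptake_high)),
                    noise = noise, t_ex = t_ex)
}

test_that("single fit recovers the generating p on noiseless envelopes", {
  env <- simulate_envelope(table1_peptide(), data.frame(fraction = 1, p = 0.3),
                           noise = noise_model(0, 0))
  fit <- fit_single_binomial(env)
  expect_equal(fit$p_hat, 0.3, tolerance = 1e-4)
  expect_lt(fit$rss / sum(env$intensity^2), 1e-10)
  expect_identical(fit$n_params, 2L)
})

test_that("zero-intensity envelopes are rejected at construction", {
  pep <- hdx_peptide("GASMKT")
  expect_error(spectral_envelope(c(100, 101), c(0, 0), pep), "total intensity")
})

test_that("single fit of a 50:50 mixture lands between the modes, matching a
           dense grid-search oracle", {
  env <- table1_envelope(0.5, 17 * 0.1 * 1.00628, 17 * 0.7 * 1.00628,
                         noise_model(0, 0), t_ex = 30)
  fit <- fit_single_binomial(env)
  # independent dense grid search over p with profiled amplitude
  pat <- natural_isotope_pattern("ALIYGAPRAATVKAKTNVKL")
  idx_mass <- (env$mz - 1.00728) * 2
  idx <- round((idx_mass - pat$masses[1]) / ((1.0033548 + 1.00628) / 2))
  basis <- function(p) {
    ab <- rep(0, length(idx))
    full <- convolve(pat$abundances, rev(dbinom(0:17, 17, p)), type = "open")
    ok <- idx >= 0 & idx < length(full)
    ab[ok] <- full[idx[ok] + 1]
    ab
  }
  orc <- oracle_single_grid(env$intensity, basis)
  expect_equal(fit$p_hat, orc$p, tolerance = 2e-3)
  expect_lte(fit$rss, orc$rss * (1 + 1e-6))
  # with a free amplitude the least-squares optimum hugs one mode; either
  # way the single model must leave substantial residual on a true mixture
  expect_true(fit$p_hat >= 0.05 && fit$p_hat <= 0.75)
  expect_gt(fit$rss / sum(env$intensity^2), 1e-3)
})

test_that("double fit recovers Table-style two-population ground truth", {
  env <- table1_envelope(0.65, 3.32, 8.65, noise_model(0, 0), t_ex = 30)
  fit <- fit_double_binomial(env)
  expect_equal(fit$frac_low, 0.65, tolerance = 0.01)
  expect_equal(17 * fit$p_low * 1.00628, 3.32, tolerance = 0.01)
  expect_equal(17 * fit$p_high * 1.00628, 8.65, tolerance = 0.01)
  expect_true(fit$p_low < fit$p_high)
})

test_that("double fit is exact for a well-separated noiseless 50:50 mixture", {
  env <- table1_envelope(0.5, 17 * 0.1 * 1.00628, 17 * 0.9 * 1.00628,
                         noise_model(0, 0), t_ex = 30)
  fit <- fit_double_binomial(env)
  expect_equal(fit$frac_low, 0.5, tolerance = 1e-4)
  expect_equal(fit$p_low, 0.1, tolerance = 1e-4)
  expect_equal(fit$p_high, 0.9, tolerance = 1e-4)
})

test_that("degenerate single-population envelopes keep rss2 <= rss1", {
  env <- simulate_envelope(table1_peptide(), data.frame(fraction = 1, p = 0.4),
                           noise = noise_model(0.01, 100, seed = 5))
  s <- fit_single_binomial(env)
  d <- fit_double_binomial(env, single = s)
  expect_lte(d$rss, s$rss * (1 + 1e-9))
})

test_that("F-test follows the nested-model formula and edge cases", {
  mk <- function(rss, n, k) list(rss = rss, n_points = n, n_params = k)
  # equal fits: no evidence
  expect_identical(f_test(mk(10, 50, 2), mk(10, 50, 5)), 1)
  # worked reference case: F = ((10-5)/3)/(5/45) = 15 on (3, 45) df
  expect_equal(f_test(mk(10, 50, 2), mk(5, 50, 5)),
               pf(15, 3, 45, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(f_test(mk(10, 4, 2), mk(5, 4, 5)), "insufficient")
  # noiseless true bimodal: overwhelming evidence
  env <- table1_envelope(0.65, 3.32, 8.65, noise_model(0, 0), t_ex = 30)
  s <- fit_single_binomial(env); d <- fit_double_binomial(env, single = s)
  expect_lt(f_test(s, d), 0.01)
})

test_that("secondary metrics: delta-chi, separation, confidence-of-fit", {
  env <- table1_envelope(0.65, 3.32, 8.65, noise_model(0.01, 20, seed = 2),
                         t_ex = 30)
  fit <- bimodal_fit(env, intensity_cv = 0.01)
  expect_equal(fit$separation, 8.65 - 3.32, tolerance = 0.1)
  expect_gt(fit$separation, 1.5)
  expect_gt(fit$delta_chi, 1)
  expect_gte(fit$reg_ci, 95)
  # identical fits give zero improvement
  s <- fit_single_binomial(env)
  met <- secondary_metrics(s, c(s, list(p_low = s$p_hat, p_high = s$p_hat)),
                           17, 100)
  expect_equal(met$delta_chi, 0)
})

test_that("classification decision tree applies primary and secondary rules", {
  th <- bimodal_thresholds()
  expect_identical(classify_envelope(0.005, 97, 50, 5.33, 0, th), "bimodal")
  expect_identical(classify_envelope(0.30, 97, 50, 5.33, 0, th), "unimodal")
  expect_identical(classify_envelope(0.30, 97, 50, 5.33, 10, th), "broadening")
  expect_identical(classify_envelope(0.03, 99, 50, 1.0, 0, th), "broadening")
  expect_identical(classify_envelope(0.03, 99, 50, 2.0, 0, th), "bimodal")
  expect_identical(classify_envelope(0.03, 99, 0.5, 5, 0, th), "broadening")
  expect_identical(classify_envelope(0.01, 80, 50, 5.33, 0, th), "broadening")
  # band boundaries: left-closed secondary band, strict primary cutoff
  expect_identical(classify_envelope(0.05, 99, 50, 5.33, 0, th), "unimodal")
  expect_identical(classify_envelope(0.02, 99, 50, 5.33, 0, th), "bimodal")
})

test_that("population fractions are only reported for bimodal envelopes", {
  env <- table1_envelope(0.65, 3.32, 8.65, noise_model(0.01, 20, seed = 3),
                         t_ex = 30)
  fit <- bimodal_fit(env, intensity_cv = 0.01)
  expect_identical(fit$classification, "bimodal")
  pf <- population_fractions(fit)
  expect_equal(pf$frac_low_pct + pf$frac_high_pct, 100, tolerance = 1e-6)
  expect_equal(pf$frac_low_pct, 65, tolerance = 5)

  uni <- simulate_envelope(table1_peptide(), data.frame(fraction = 1, p = 0.3),
                           noise = noise_model(0, 400, seed = 4))
  ufit <- bimodal_fit(uni)
  expect_false(ufit$classification == "bimodal")
  expect_error(population_fractions(ufit), "bimodal")
})

test_that("fraction recovery within 3 points under 1%-of-max noise", {
  errs <- vapply(1:25, function(i) {
    env <- table1_envelope(0.65, 3.32, 8.65,
                           noise_model(0.01, 20, seed = 300 + i), t_ex = 30)
    fit <- fit_double_binomial(env)
    abs(100 * fit$frac_low - 65)
  }, numeric(1))
  expect_lt(mean(errs), 3)
  expect_lt(max(errs), 6)
})

test_that("p_low < p_high ordering holds across random mixtures", {
  set.seed(77)
  for (i in 1:8) {
    fl <- runif(1, 0.2, 0.8)
    u1 <- runif(1, 1, 5); u2 <- u1 + runif(1, 2, 5)
    env <- table1_envelope(fl, u1, u2, noise_model(0.01, 20, seed = 500 + i),
                           t_ex = 30)
    fit <- fit_double_binomial(env)
    expect_lt(fit$p_low, fit$p_high)
  }
})

test_that("low signal-to-noise envelopes are flagged instead of classified", {
  env <- table1_envelope(0.65, 3.32, 8.65,
                         noise_model(0, 2000, seed = 6), t_ex = 30)
  fit <- bimodal_fit(env)
  expect_lt(fit$snr, 250)
  expect_identical(fit$classification, "low_snr")
  expect_error(population_fractions(fit), "bimodal")
})

test_that("bimodal report mirrors the per-envelope layout", {
  sched <- data.frame(t_ex_min = c(10, 30), frac_low = c(0.856, 0.65),
                      uptake_low = c(2.8, 3.32), uptake_high = c(7.79, 8.65))
  envs <- simulate_bimodal_series(table1_peptide(), sched, n_replicates = 2,
                                  noise = noise_model(0.01, 20, seed = 9))
  rep <- bimodal_report(envs, intensity_cv = 0.01)
  expect_identical(nrow(rep), 4L)
  expect_true(all(rep$classification == "bimodal"))
  expect_equal(rep$frac_high_pct[rep$t_ex_min == 30], c(35, 35), tolerance = 0.1)
  expect_true(all(abs(rep$frac_low_pct + rep$frac_high_pct - 100) < 1e-6))
})
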