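# hdxpop

Peptide-level analysis of hydrogen/deuterium exchange mass spectrometry
(HDX-MS) for proteins that populate two slowly interconverting states —
typically a ligand-bound, low-exchanging conformation and a ligand-free,
high-exchanging one — plus Michaelis–Menten analysis of the linked enzyme
assays that usually accompany such studies. It is written for HDX-MS
practitioners who have peptide-level spectral envelopes and uptake tables
and want population-resolved, statistically guarded answers rather than
centroids alone.

## What it computes

**Deuterium uptake.** For a peptide envelope the centroid is the
intensity-weighted mean m/z converted to neutral mass; uptake is

    D(t) = centroid(deuterated, t) − centroid(undeuterated)   [Da]

with replicate mean ± sample SD, after the standard identification filters
(intensity ≥ 5000, length 5–25, |mass error| ≤ 10 ppm, ≥ 1 product,
≥ 2 files).

**Differential exchange.** Per peptide and timepoint,
ΔD = D_state − D_reference with errors propagated in quadrature; |ΔD| >
0.5 Da (strict) is flagged significant, negative = protection, positive =
deprotection.

**Bimodal deconvolution.** Each envelope is fit with one binomial,
A·(isotope pattern ⊛ Binomial(n_ex, p)), and with a sum of two binomials
(p_low < p_high). Models are compared with the nested F-test

    F = ((RSS₁ − RSS₂)/(k₂ − k₁)) / (RSS₂/(n − k₂)),  F(3, n−5)

plus overfitting guards: a regression confidence (>95%), the centroid
separation of the two sub-envelopes (>1.5 Da), and the Δχ² improvement,
applied in the 0.02 ≤ p < 0.05 band. Envelopes classify as unimodal,
broadening or bimodal; bimodal ones report population fractions and
per-population uptakes, the digest of an EX1-type population analysis.

**Population kinetics.** The bound-fraction time course is fit with
f(t) = exp(−k t) (f(0)=1 fixed, t-weighted log-linear least squares);
t½ = ln 2 / k is the ligand-release half-life.

**Enzyme kinetics.** v = V_max·S/(K_M + S) by Levenberg–Marquardt least
squares; k_cat = (V_max·10³/[E])/60 for V_max in μM/min and [E] in nM, and
variant contrasts as percent reduction in k_cat.

A seeded synthetic-data generator (`simulate_envelope()`,
`simulate_bimodal_series()`, `simulate_two_state_uptake()`,
`simulate_mm_assay()`) shares the forward model with the fitters and
produces every input the pipeline needs, so the whole analysis is testable
end-to-end without raw instrument files.

## Worked example

```r
library(hdxpop)

pep <- hdx_peptide("ALIYGAPRAATVKAKTNVKL", start = 202, end = 221, charge = 2)
env <- simulate_envelope(pep,
  populations = data.frame(fraction = c(0.65, 0.35), uptake = c(3.32, 8.65)),
  noise = noise_model(intensity_cv = 0.01, baseline_sd = 20, seed = 1),
  t_ex = 30)
bimodal_fit(env, intensity_cv = 0.01)
#> Bimodal deconvolution fit
#>   peptide 202-221 ALIYGAPRAATVKAKTNVKL (+2), t_ex = 30 min
#>   classification: bimodal (F-test p = 3.21e-50)
#>   low-exchanging:  3.33 Da  65.3%
#>   high-exchanging: 8.69 Da  34.7%
```

The envelope was generated as a 65:35 mixture of populations at 3.32 and
8.65 Da uptake with 1% intensity noise; the fit classifies it bimodal and
recovers the fractions and uptakes to within a fraction of a percentage
point / hundredth of a Da.

```r
release_fit(c(10, 30), c(0.856, 0.65))
#> Release kinetics: k = 0.0144 min^-1, t1/2 = 48.1 min (2 timepoints)
```

Bound fractions of 85.6% and 65% at 10 and 30 min give a ligand-release
half-life of ~48 min — slow release on the scale of the exchange
experiment.

```r
assay <- simulate_mm_assay(1.13, vmax = 0.12, cv = 0.05, seed = 1, variant = "WT")
mm_fit(assay$substrate_uM, assay$rate_uM_per_min, variant = "WT")
#> Michaelis-Menten fit (WT, 1 nM enzyme)
#>   Km   = 1.086 +/- 0.066 uM
#>   Vmax = 0.1194 +/- 0.0022 uM/min
#>   kcat = 1.990 s^-1
```

Triplicate rates over 0.25–10 μM substrate at 5% CV recover the generating
parameters (K_M 1.13 μM, V_max 0.12 μM/min, k_cat 2.0 s⁻¹) within their
standard errors.

`run_hdx_pipeline(hdx_pipeline_config(seed = 1), outdir = "run1")` wires
all stages together and writes CSV report tables plus a JSON manifest.

## Package layout

- `R/` — forward model (`natural_isotope_pattern`, `deuterated_envelope`,
  `centroid`), uptake and differential tables, the `bimodal_fit`,
  `release_fit` and `mm_fit` S3 fitting functions with their methods, the
  synthetic generator and `run_hdx_pipeline`.
- `tests/testthat/` — unit, property and end-to-end recovery tests with
  brute-force enumeration oracles in the helpers.
- `vignettes/hdx-population-analysis.Rmd` — the methods vignette: model
  assumptions, thresholds, noise model, numerical choices, limitations.
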