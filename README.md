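# drsmargin

Quantitative diffuse reflectance spectroscopy (DRS) for breast tumor margin
assessment: a Monte Carlo model of fiber-probe reflectance, inverse
extraction of tissue composition, and longitudinal statistics for how the
optical contrast of excised tissue decays on the bench.

## The problem

Breast-conserving surgery aims to remove the tumor with a clear rim of
normal tissue, but a large fraction of patients need re-excision because
positive margins are found only at post-operative pathology. Visible-band
DRS imaging can map margin composition intra-operatively through three
contrast sources: total hemoglobin concentration [THb] (vascularity),
beta-carotene concentration (adipose content), and the band-averaged reduced
scattering coefficient ⟨µs′⟩ (fibroglandular content). Before such maps can
be trusted, three surgical confounders must be quantified: the **time after
excision** (endpoints drift as blood drains and the tissue equilibrates),
**cautery** (sealed vasculature on lumpectomy surfaces), and **patent blue
dye** injected for sentinel-node mapping, whose absorption overlaps the
hemoglobin alpha/beta bands. `drsmargin` implements that quantification as a
reproducible pipeline for anyone building or validating optical
margin-assessment tools.

## What is inside

* **Spectral core** — Beer's-law absorption
  µa(λ) = Σᵢ εᵢ(λ)·cᵢ over HbO₂, HbH, beta-carotene and patent blue dye
  (packaged extinction tables, 450–600 nm), and power-law scattering
  µs′(λ) = a·(λ/500 nm)⁻ᵇ with analytic calibration of the band average
  ⟨µs′⟩.
* **Forward model** — seeded Monte Carlo photon transport under a
  multi-fiber contact probe (Henyey–Greenstein scattering, Fresnel
  boundary, NA-limited launch and collection), accelerated by a
  white-medium baseline whose stored trajectories are similarity-rescaled
  to any (µa, µs′): R = Σ w·P(r·s)·e^(−µa·s·L) / N.
* **Inversion** — bounded Levenberg–Marquardt least squares recovering
  (HbO₂, HbH, beta-carotene, dye, a, b) from a calibrated spectrum, with
  Latin-hypercube multi-start and a deterministic scattering-power profile
  that escapes a known spurious boundary minimum; endpoints [THb], HbSat,
  ⟨µs′⟩ and the ratios [beta-carotene]/⟨µs′⟩, [THb]/⟨µs′⟩.
* **Dye robustness study** — the 3×3×3×8 factorial (216 spectra) crossing
  the clinical quartile levels of ⟨µs′⟩, [THb] and [beta-carotene] with
  0–70 µM dye, plus a 12-step liquid-phantom titration analogue (0–79 µM),
  tabulating signed percent errors of every extraction.
* **Kinetics** — linear mixed-effects models (random intercept and slope
  per site) of endpoint time series; the percent-change statistic
  100·slope/|intercept|·t; Wilcoxon cautery comparisons; likelihood-ratio
  tests for tissue-type dependence of the rates; Spearman
  first-measurement drift; contrast-decay maps.
* **Synthetic cohort generator** — seeded lumpectomy/mastectomy cohorts
  with the published sample sizes, measurement cadences, baseline quartiles
  and kinetic rates, retaining the generating truth for recovery tests.
* **CLI** — `inst/cli/drsmargin` with `synth`, `dye-study` and `kinetics`
  subcommands, writing CSV results and a JSON manifest with checksums.

## Worked example

Simulate a spectrum at known composition, invert it, and read the
endpoints back:

```r
library(drsmargin)

lib  <- load_extinction_library()
grid <- wavelength_grid()                         # 450-600 nm, 5 nm steps
base <- build_baseline(cfg = mc_config(photon_count = 1e5, rng_seed = 42))

concs <- chromophore_concentrations(HbO2 = 8.485, HbH = 8.485,
                                    beta_carotene = 10.29,
                                    patent_blue_dye = 40)
scat  <- calibrate_amplitude(4.85, b = 1.2, grid = grid)
props <- optical_properties(grid, compose_mua(concs, lib, grid),
                            musp_power_law(scat, grid))
spec  <- simulate_spectrum(props, base = base)

fit <- fit_spectrum(spec, lib, base, seed = 1)
unlist(fit$endpoints[c("THb", "beta_carotene", "dye", "mean_musp")])
#>           THb beta_carotene           dye     mean_musp
#>         16.97         10.29         40.00          4.85
```

The fit recovers [THb] = 16.97 µM, [beta-carotene] = 10.29 µM, 40 µM of
dye and ⟨µs′⟩ = 4.85 cm⁻¹ — the values the spectrum was simulated with —
even though 40 µM of patent blue dye dominates the long-wavelength
absorption. Ran over the full 216-point factorial, the largest absolute
extraction error in [THb], [beta-carotene] and ⟨µs′⟩ stays far below 3.3%
at every dye level.

On the kinetics side:

```r
cfg    <- calibrate_defaults()
cohort <- generate_cohort(cfg, seed = 1, classes = "lumpectomy_benign")
fit    <- fit_longitudinal(cohort$data, "THb")
percent_change(fit, 30)$median
#> [1] -40.0
time_to_contrast_loss(-44.2, -92.3, 30)$minutes
#> [1] 63
```

The first number is the cohort median 30-minute percent change in [THb]
for one seeded 59-site benign lumpectomy cohort (the calibrated expectation
is −44.2%; single cohorts scatter around it). The second is how long it
would take a −44.2%/30 min decline to consume the −92.3% fibroglandular
versus positive-margin difference: 63 minutes, i.e. [THb] contrast
survives any realistic imaging delay.

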