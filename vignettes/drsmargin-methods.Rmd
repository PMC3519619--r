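---
title: "Models and methods behind drsmargin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drsmargin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsmargin)
```

`drsmargin` reproduces, as a tested pipeline, a quantitative
diffuse-reflectance workflow for assessing breast tumor margins: a Monte
Carlo forward model of probe-collected reflectance, an inverse model that
extracts tissue chromophores and scattering from a measured spectrum, a
factorial robustness study of those extractions in the presence of the
sentinel-node mapping dye (patent blue / Lymphazurin), and a longitudinal
mixed-effects analysis of how the optical endpoints of excised tissue decay
with time on the bench. Because no clinical spectra are distributed, a
seeded synthetic-cohort generator supplies data with the statistical
structure the analyses assume. This vignette documents the models, the
tunable parameters, the numerical choices, and the limits of what the tests
demonstrate.

## The optical model

Tissue absorption over 450-600 nm is composed by Beer's law from four
absorbers — oxy-hemoglobin, deoxy-hemoglobin, beta-carotene, and patent blue
dye —

$$\mu_a(\lambda) = \sum_i \varepsilon_i(\lambda)\, c_i ,$$

with concentrations $c_i$ in µM and natural-log extinction spectra
$\varepsilon_i$ in cm$^{-1}$µM$^{-1}$. The shipped extinction tables are
smooth interpolants anchored on the public Prahl compilation for the
hemoglobins and beta-carotene; the patent blue dye spectrum is a *synthetic*
approximation (a single band peaking near 635 nm whose rising edge overlaps
the hemoglobin alpha/beta bands), because no reference curve is published.
The loader converts units and log base as declared in the JSON sidecar, so
decadic sources acquire their $\ln 10$ exactly once. Crocin, the
beta-carotene substitute used in liquid phantoms, is represented by the
beta-carotene table.

Every quantitative claim the package tests is *forward/inverse
self-consistent*: the same library drives simulation and inversion, so
results depend on using one set of tables consistently, not on their
absolute accuracy.

Reduced scattering follows a power law
$\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b}$ with $\lambda_0 = 500$ nm.
The scalar endpoint $\langle\mu_s'\rangle$ is the 450-600 nm average, and
`calibrate_amplitude()` inverts the band average analytically (round trip
below $10^{-9}$ relative). The default power $b = 1.2$ is a typical
soft-tissue value; only $\langle\mu_s'\rangle$ is treated as a published
quantity.

## Photon transport and the scaled baseline

`run_direct_mc()` transports photons through a homogeneous semi-infinite
medium: Henyey-Greenstein scattering with $g = 0.9$, steps drawn from
$\mu_s = \mu_s'/(1-g)$ (similarity parameterization, so everything is
indexed by $\mu_s'$), continuous-weight absorption, Fresnel reflection at a
flat interface ($n_\mathrm{tissue} = 1.37$ against a fused-silica probe
face of 1.45; both configurable), Russian roulette below weight $10^{-4}$
with survival 0.1, and a 5 cm pathlength cutoff. One probe channel is
modelled: a 1 mm illumination core (19 fibers treated as a uniformly
emitting disk) and four 200 µm collection fibers whose implied
source-detector separations stay within the probe's 0.23-1.10 mm span.
Launch directions populate the NA 0.22 cone (refracted into the medium) and
exits must fall within the same cone. Collection is evaluated by an
azimuthally averaged *collection profile* $P(r)$ — the probability that an
exit at lateral displacement $r$ from its launch point lands on a collection
fiber — precomputed by deterministic quadrature, which removes the azimuthal
variance from the estimator.

Photon counts, phase function, anisotropy, and refractive indices are not
published for the original forward simulations; the defaults above are
declared choices, not inferences.

A full simulation per wavelength would be wasteful, so `build_baseline()`
runs the transport once, in a *white* (zero-absorption) medium at the
reference scattering level $\mu_s'_{\mathrm{ref}} = 6.68$ cm$^{-1}$ (the
clinical median), and stores each NA-accepted exit as (radius, pathlength).
`scale_reflectance()` then maps the stored trajectories to any target
properties: similarity rescaling shrinks radius and pathlength by
$s = \mu_s'_{\mathrm{ref}}/\mu_s'$, and absorption enters analytically as
$e^{-\mu_a s L}$. Running the baseline white (rather than at a small
reference absorption, with the reference attenuation divided back out) makes
the identity case exact and keeps stored weights absorption-free; the
reference $\mu_a$ is recorded in metadata only. The validated scaling span
is 0.25-4x the reference. For the inversion's inner loop the records are
compressed onto a 120 x 60 (radius x log-pathlength) grid with
weight-averaged cell coordinates; the compression agrees with raw-record
evaluation to well under 1%, and both forward simulation and inversion
evaluate the *same* compressed representation, so round-trip studies are
exact up to the optimizer. Scaled and direct estimates agree within Monte
Carlo error across the study's scattering and absorption levels, and the
radially resolved exit density at the far separation matches dipole
diffusion theory within 15% in the diffusive regime — both are automated
tests.

## Inversion

`fit_spectrum()` minimizes the unweighted squared residual between the
measured reflectance and the model — Beer's-law absorption plus power-law
scattering pushed through the scaled baseline — over
$\theta = (c_{\mathrm{HbO_2}}, c_{\mathrm{HbH}}, c_{\beta\mathrm{car}},
c_{\mathrm{dye}}, a, b)$ with bounds covering the clinical quartiles and the
72.7 µM clinical dye maximum with headroom ($c_\mathrm{Hb}$ up to 200 µM,
others to 100 µM, $b \in [0, 3]$, $a$ confined to the baseline's validated
scaling span). Optimization is bounded Levenberg-Marquardt from seeded
Latin-hypercube starts (5 by default), best residual wins, ties to the
lowest start index. Two numerical hazards are handled explicitly:

* **A spurious boundary minimum.** The surface carries a local minimum in
  which the scattering power pins at a bound while beta-carotene and the
  hemoglobin split compensate; it sits at a clearly nonzero residual
  (relative norm around $10^{-2}$ versus $10^{-15}$ at the global optimum on
  noise-free data). When the best residual stays above `retry_threshold`,
  the fitter runs a deterministic profile over eleven fixed scattering
  powers (five-parameter fits), releases all six parameters from the best
  profile point, and only then falls back to additional random starts.
* **Noise weighting.** For data with multiplicative noise the
  `objective = "log"` flag fits log-reflectance, which weights every channel
  by relative deviation — the maximum-likelihood choice under that noise
  model. The default remains the plain reflectance objective; the phantom
  titration (whose declared noise is multiplicative) uses the log objective.

With six free parameters and a single source-detector geometry the problem
is intrinsically ill-conditioned under noise: linearized analysis at the
phantom recipe gives a ~5% relative standard deviation in beta-carotene per
1% of measurement noise (dominated by the beta-carotene-versus-$b$
trade-off), versus ~1.5% with $b$ fixed. The tests therefore bound the
scattering endpoint (the best-conditioned one, within 5% at 1% noise across
the titration) and the noise-free factorial (all endpoints below 3.3%), and
the vignette flags the beta-carotene noise sensitivity as a real property of
this parameterization rather than a defect.

HbSat is computed from every fit but excluded from the linear kinetics
below: oxy- and deoxy-hemoglobin change too quickly and non-linearly after
excision for a linear model, so only THb, beta-carotene,
$\langle\mu_s'\rangle$, the two ratios, and dye are carried forward.

## The dye robustness study

`build_design()` crosses the published clinical quartile levels —
$\langle\mu_s'\rangle \in \{4.85, 6.68, 9.15\}$ cm$^{-1}$,
THb $\in \{16.97, 31.03, 55.09\}$ µM, beta-carotene
$\in \{10.29, 16.29, 24.37\}$ µM — with dye from 0 to 70 µM in 10 µM steps:
216 points. THb is split 50/50 into oxy/deoxy for simulation (the design
specifies THb only; the split is symmetric and declared). Each spectrum is
simulated through the shared baseline, inverted with the same library, and
the signed percent error recorded for THb, beta-carotene,
$\langle\mu_s'\rangle$ and dye; the dye-free column's dye error is undefined
and reported as the extracted concentration instead. Maximum absolute errors
sit at numerical-convergence level (about $10^{-6}$%), comfortably inside
the 3.3% bound, with no trend in dye — the substantive finding being
reproduced. The phantom titration analogue uses the printed recipe
($\langle\mu_s'\rangle$ 5.81 cm$^{-1}$, THb 16.69 µM, beta-carotene
11.23 µM, dye 0-79 µM in 12 titrations) with 1% multiplicative noise
standing in for experimental measurement error.

## Kinetics

`fit_longitudinal()` fits, per endpoint, a linear mixed model with fixed
effects for time and histology subtype (plus an optional
diagnosis-by-time interaction) and a correlated random intercept and slope
per site, by REML through `lme4`. The published analysis states only
"longitudinal mixed-effects model"; random intercept *and* slope is the
structure that yields a fitted slope for every site, and per-site lines are
BLUPs (fixed plus random), evaluated by prediction at $t = 0$ and $t = 1$
so histology effects are included. The percent-change statistic is
$100 \cdot \mathrm{slope} / |\mathrm{intercept}| \cdot t$ — exactly linear
in the horizon, so the 10/20/30-minute columns satisfy
$\mathrm{pct}_{10} = \mathrm{pct}_{30}/3$ identically. Cautery comparisons
are Wilcoxon rank-sum tests on first-measurement values and on per-site
rates refit within each site's first 10 minutes; tissue-type dependence is a
maximum-likelihood likelihood-ratio test on the diagnosis-by-time term;
first-measurement drift is a Spearman correlation. Significance is taken at
$p < 0.05$ with no multiplicity correction, mirroring the source analysis;
reports say so.

A small-sample caveat, measured rather than assumed: at the mastectomy
cohort's size (13 benign + 7 malignant sites) the chi-square LRT is
anticonservative — about 12% type-I error at nominal 5% over 200 null
simulations. Calibration-type tests (null type-I within [0.025, 0.075],
p-uniformity, shared-rate non-significance) therefore run on a 30+30-site
null cohort where the asymptotics hold (measured type-I ~6%); the
paper-sized cohort is checked qualitatively (non-significant in the
majority of seeds). This is a property of the test at that sample size, not
of the implementation.

## The synthetic cohort generator

The generator emits endpoint time series directly (an end-to-end flag can
route truth through the forward model and inversion instead, at much higher
cost). Its defaults encode the study conditions:

* **Counts and histology:** 59 benign lumpectomy sites (1 FG, 2 FA, 29
  adipose, 27 mixed/other), 13 benign and 7 malignant mastectomy sites.
* **Cadence:** lumpectomy first measurement 7±3 min truncated to [2, 12],
  intervals uniform on [0.86, 1] min (mean 0.93), series 10-21 min;
  mastectomy 17±4 min in [10, 27], intervals mean 0.42 min, series
  10-32 min.
* **Baselines:** log-normal per endpoint. Dispersions are matched to the
  published quartiles (e.g. $\sigma_{\log} = \log(55.09/16.97)/(2 z_{0.75})$
  for THb); endpoints without published quartiles (the ratios, dye) carry
  declared dispersions (0.5, 1.0). Medians are *calibrated*: the expected
  59-site sample median of the 30-minute percent change equals the published
  medians (-8.2% beta-carotene, -13.8% $\langle\mu_s'\rangle$, +8.0%
  beta-carotene ratio, -44.2% THb, -40.8% THb ratio). The sample-median
  (order-statistic) target rather than the population median matters because
  the percent-change distribution is heavy-tailed.
* **Rates:** per-class normal distributions with the published means and
  SDs (benign lumpectomy THb $-0.537 \pm 0.750$ µM/min, and so on). Each
  site's rate is coupled to its baseline by *opposite ranks* — the
  highest-baseline sites decline fastest. This keeps declines from driving
  endpoints negative inside the measurement window (the marginal rate
  distribution is untouched, so the published mean±SD is preserved), and it
  makes the median-percent-change calibration exact by construction.
* **Dye washout:** slope proportional to the site's own intercept, with the
  implied 30-minute percent change equal to -228.7% for every site; series
  floor at zero once drained. A structural note: for any non-negative,
  floored series observed on this cadence, the per-site least-squares line
  cannot cross zero before $t_\mathrm{first} + \tfrac{2}{3}\,\mathrm{duration}$,
  which caps the *recovered* percent change near
  $-3000/(7 + 10.3) \approx -170\%$; the published -228.7% reflects the
  ratio instability of near-zero real dye intercepts. The generator encodes
  the true (implied) change; the pipeline's recovered median (about -160%)
  is reported as computed, and the gap is a documented property of the
  statistic, not a calibration error.
* **Cautery contrast:** benign mastectomy THb baselines are 2.5x lower than
  the (cauterized) lumpectomy baselines, and dye 3x lower — declared
  magnitudes chosen to give a clearly detectable first-measurement
  difference in the published direction; the published clinical effect
  sizes are unpublished.
* **Malignant offsets:** malignant medians are the benign medians times
  $(1 - d/100)$ with $d$ the published adipose-versus-positive percent
  differences (so THb roughly doubles and beta-carotene drops by ~30% in
  malignant tissue).
* **Noise:** multiplicative Gaussian, $\sigma = 2\%$ per observation,
  independent across timepoints — a declared choice; the source reports no
  noise model.

What the generator does **not** emulate: non-linear (e.g. exponential)
kinetics within the window, spatial histology beyond smooth log-normal
random fields in the margin maps, probe-contact failures, instrument drift,
or between-patient correlation of sites (sites are independent). Passing
tests therefore demonstrate that the *analysis machinery* recovers known
structure under the declared conditions — not that real tissue obeys them.

Margin maps (`generate_margin_maps()`) are smooth log-normal fields centered
on the class medians with the malignant offsets above;
`contrast_decay_map()` multiplies a map by $(1 + \mathrm{pct}/100)$ and can
upsample by separable cubic splines for rendering. Applying the published
30-minute decays leaves the benign-malignant contrast intact — decayed
beta-carotene on a negative margin stays above a positive margin, and
decayed THb on a positive margin stays above a negative one.

## Problem sizes and determinism

Default problem sizes are desk-scale by design: $10^5$ photons for the
shared baseline (the factorial and its inversions are self-consistent, so
baseline noise cancels), $4 \times 10^5$-$10^6$ photons where scaled and
direct estimates are compared, 20 seeded cohorts for recovery studies, 200
seeds for null calibration. Every stochastic stage — transport, start-point
jitter, cohort draws, noise — is driven by explicit integer seeds through
R's RNG, and identical inputs reproduce outputs bit-for-bit; study drivers
derive per-unit seeds from the master seed so that runs are reproducible
end to end.
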