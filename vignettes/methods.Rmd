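---
title: "Models and methods behind neoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoflow)
```

neoflow implements the analysis chain of a hybrid frequency-domain NIRS +
diffuse correlation spectroscopy (FDNIRS–DCS) neuromonitor, of the kind used
to characterize cerebral hemodynamics in term newborns, together with a
synthetic-cohort generator built on the same physics. This vignette explains
the models, the assumptions behind each stage, the tunable parameters and
their defaults, the numerical choices, and what validation on synthetic data
does and does not establish.

## Photon diffusion: the FDNIRS stage

Intensity-modulated light (110 MHz) in a highly scattering medium behaves as
a damped spherical wave — a diffuse photon density wave. In the semi-infinite
reflection geometry, at source–detector distances large compared with one
transport mean free path, the model predicts

$$\ln\!\big(AC\cdot\rho^2\big) = \text{const} - k_{re}\,\rho,\qquad
  \phi(\rho) = \phi_0 + k_{im}\,\rho,$$

with the complex DPDW wavenumber components

$$k_{re,im} = \sqrt{\frac{3\mu_a\mu_s'}{2}
  \Big(\sqrt{1+(\omega/v\mu_a)^2}\pm 1\Big)},$$

where $v = c/n$ is the light speed in tissue. These satisfy two exact
identities, $k_{re}^2-k_{im}^2 = 3\mu_a\mu_s'$ and
$k_{re}k_{im} = 3\mu_s'\omega/2v$, which give the closed-form inversion used
by `multidistance_fit()`:

$$\mu_s' = \frac{2v}{3\omega}S_{AC}S_\phi,\qquad
  \mu_a = \frac{\omega}{2v}\Big(\frac{S_{AC}}{S_\phi}-\frac{S_\phi}{S_{AC}}\Big).$$

Assumptions: homogeneous semi-infinite tissue, $\mu_s' \gg \mu_a$ (diffusion
regime), distances in the multi-distance linear regime. Slope fitting is
unweighted ordinary least squares; since the identities above are exact under
the diffusion model, the small absorption correction sometimes folded into
the scattering recovery (from defining the diffusion coefficient with a
$-\mu_a$ term) is unnecessary and omitted — a convention, not an
approximation, under $D = v/3\mu_s'$.

**Calibration.** Amplitude units are arbitrary per channel; each
(wavelength × distance) channel carries an unknown gain and phase offset.
`calibrate()` removes them by comparing median phantom measurements against
the model prediction for the phantom's known optical properties:
`gain = predicted/measured`, `offset = measured − predicted`. Applying the
factors and re-inverting the phantom reproduces its known coefficients
exactly in the noise-free case (a test).

**Temporal reduction.** Each 10 s acquisition yields ~100 samples per
channel (10 Hz); `temporal_median()` reduces them to medians, which are
robust to transient artifacts. "Phase noise" is not uniquely defined by
common usage; here it is the standard deviation of the ~100 phase samples of
a channel, and the quality threshold is applied to the worst channel entering
a slope fit. The alternative (an aggregate across channels) would be more
permissive; the worst-channel rule is the conservative reading.

**Quality control.** A wavelength's slope fit is kept iff worst-channel
phase noise ≤ 0.05 rad and both regression R² ≥ 0.95, with comparisons
inclusive on the keep side (a value exactly at a threshold is kept). Both
thresholds are configurable in `run_config()`.

## Spectral stage

Absorption is modeled as a nonnegative mixture of oxyhemoglobin,
deoxyhemoglobin and 75% water,
$\mu_a(\lambda)=\varepsilon_{HbO}\,C_{HbO}+\varepsilon_{HbR}\,C_{HbR}
+0.75\,\mu_{a,H_2O}$. `fit_chromophores()` subtracts the water term and
solves the two-chromophore nonnegative least-squares problem (an active-set
step — with two variables, clamping any negative coefficient to zero and
refitting the other is exact). Concentrations are constrained nonnegative
because negative concentrations are unphysical; the unconstrained solution is
used whenever it is already feasible, so the constraint never distorts
well-posed data.

The bundled extinction table (`inst/extdata/extinction_coefficients.csv`)
carries Napierian extinction coefficients in cm⁻¹ per µM at the 8 instrument
wavelengths and 850 nm, transcribed (with interpolation) from the standard
hemoglobin compendium, plus pure-water absorption from the standard optical
survey; its header documents units and provenance. Absolute accuracy of
these entries matters only for real data: every synthetic recovery result in
this package uses the same table in the forward and inverse directions and
is therefore invariant to its values (this is itself asserted by a
consistency test).

Scattering follows the Mie-derived power law
$\mu_s'(\lambda)=a\,(\lambda/500\,\text{nm})^{-b}$, where $b$ (scattering
power) reflects effective scatterer size and $a$ scatterer density.
`fit_scattering_model()` fits it as a linear regression in log–log space —
chosen over original-scale nonlinear least squares because it is exact on
data generated by the power law and has no iteration or starting-value
failure modes; agreement of the two estimators on clean spectra is checked
against a nonlinear optimizer in the tests.

Spectral fit quality uses the regression F-test p-value (the fit "p-value"
is otherwise undefined) and R²; the keep rule is p ≤ 0.03 and R² ≥ 0.6,
inclusive. For the chromophore fit R² is the squared correlation between the
measured and reconstructed absorption spectrum. On numerically perfect fits
(residual sum of squares below 1e-24) the p-value is set to 0 rather than
left indeterminate.

Both fitted models are evaluated at 850 nm (`extrapolate_to_dcs()`) to
supply the DCS stage with optical properties at its operating wavelength.

## Correlation diffusion: the DCS stage

Moving red blood cells decorrelate the speckle field; modeling their motion
as effective Brownian diffusion with coefficient CBFi (cm²/s), the
semi-infinite correlation-diffusion solution is

$$G_1(\rho,\tau)=\frac{3\mu_s'}{4\pi}\Big[\frac{e^{-K(\tau)r_1}}{r_1}
 -\frac{e^{-K(\tau)r_b}}{r_b}\Big],\qquad
 K(\tau)=\sqrt{3\mu_a\mu_s'+6\mu_s'^2k_0^2\,\text{CBFi}\,\tau},$$

with $r_1=\sqrt{\rho^2+(1/\mu_s')^2}$,
$r_b=\sqrt{\rho^2+(1/\mu_s'+2z_b)^2}$. The $K(\tau)$ used here is the
standard correlation-diffusion form for Brownian dynamics (the decay term
scales with $\mu_s'^2$); published renderings of this equation are sometimes
typographically garbled, and this package deliberately follows the canonical
form from the correlation-diffusion literature.

Constants that the model needs but that are conventions rather than
measurements:

* refractive index n = 1.4 (generic soft-tissue value) and $v=c/n$;
* extrapolated zero boundary $z_b = (2/3\mu_s')(1+R_{eff})/(1-R_{eff})$ with
  $R_{eff} = 0.493$, the effective-reflection approximation for n = 1.4;
* $k_0 = 2\pi n/\lambda$ at λ = 850 nm.

`fit_cbfi()` minimizes the sum of squared deviations between the averaged
measured $g_2$ and $1+\beta g_1^2$ over (CBFi, β) with the Nelder–Mead
simplex (`stats::optim`), matching the derivative-free approach standard in
this field. Numerical choices: CBFi is log-parameterized to enforce
positivity; β is initialized from the early-lag plateau (mean of the first
three $g_2$ values minus 1, clamped to [0.01, 1]) and CBFi at 1e-8 cm²/s (a
typical neonatal value); relative tolerance 1e-10 and at most 2000
iterations; the full lag grid is fitted by default with optional clipping. A
flat curve ($g_2\equiv 1$) carries no decay information: the fit is flagged
`degenerate` and β collapses toward 0. Fit failures are retained with
`converged = FALSE` rather than silently dropped.

By default the DCS fit uses each measurement's own FDNIRS-derived
$\mu_a(850)$ but a *fixed* $\mu_s'(850) = 6.4$ cm⁻¹ — the cohort-average
value — because propagating per-measurement scattering noise into the flow
index is the dominant error amplifier (underestimated scattering inflates
CBFi, a sensitivity asserted in the tests). `use_measured_musp = TRUE`
switches to per-measurement scattering for sensitivity analyses.

## Hemodynamic derivation

With pulse-oximeter arterial saturation SaO2 and the optical tissue
saturation SO2, assuming the optical signal mixes compartments as
$SO_2=(1-\gamma)SaO_2+\gamma SvO_2$:

$$OEF=\frac{SaO_2-SO_2}{\gamma\,SaO_2},\qquad
  CMRO_{2i}=\text{CBFi}\,(SaO_2-SO_2).$$

The venous fraction γ is a modeling assumption, not a measurement; the field
convention 0.75 is the default, it is exposed in `run_config()`, and the
derivation output records the value used. Note CMRO2i is γ-invariant while
OEF scales as 1/γ (asserted as a property test). CMRO2i is reported without
blood-hemoglobin scaling by default — within-cohort comparisons do not need
HGB, which is not routinely drawn from healthy neonates; supplying `hgb`
adds CaO2 = κ·HGB·SaO2 and absolute CMRO2 with κ = 1.34 mL O2/g. Records
with SO2 > SaO2 (negative extraction) are flagged, not discarded.

## The synthetic cohort: what it emulates

`simulate_cohort()` generates a full study: 30 term infants (19 male, 11
female), gestational age 39.2 ± 1.2 weeks truncated to the term range
[37, 42], postnatal age ~2.4 days, 7 cortical sites (left/middle/right
frontal; left/right temporal and parietal), 3 probe repositionings per site,
and for every measurement the raw data the instrument would record: 8
wavelengths × 4 distances × 100 amplitude/phase samples, and 12 intensity
autocorrelation curves on a 128-point log-spaced lag grid.

Baseline physiology sits at the population means this instrument class
reports for healthy term neonates — HbT 54 µM, SO2 0.66, a = 13.7 cm⁻¹,
b = 1.43, CBFi 2.1×10⁻⁸ cm²/s, β = 0.5, water fraction 0.75 — and the
effect structure mirrors the reported findings:

* a multiplicative right/left factor on CBFi, default 1.152 (+15.2%);
* multiplicative female/male factors on HbT, SO2, CBFi. The study reports
  directions and significance but not effect sizes, so the defaults
  (0.88, 0.93, 1.18) were chosen once as magnitudes that are physiologically
  plausible and borderline-detectable at n = 30 — consistent with p-values
  in the 0.005–0.05 range rather than overwhelming effects;
* additive per-week gestational-age slopes on HbT (7 µM/week) and SO2
  (0.05/week), centered at the GA mean. These defaults were chosen so that,
  combined with the default between-subject spread, the subject-level
  GA correlation lands in the moderate range (R ≈ 0.4–0.6) reported for
  such cohorts — a calibration of the generator, verified only as a broad
  band in the tests.

Between-subject variability uses log-normal draws for strictly positive
quantities (HbT, CBFi, a, b) and a logit-normal draw for SO2, which keeps
every draw inside its physical domain; probe repositioning adds smaller
measurement-level draws of the same form; arterial saturation is uniform in
[0.95, 0.99]. Instrument noise is Gaussian on ln-amplitude (σ = 0.02) and
phase (σ = 0.02 rad) per FDNIRS sample and on each $g_2$ bin (σ = 0.005),
and fixed per-channel gain/phase distortions (log-SD 0.3, SD 0.2 rad) are
shared with the simulated calibration phantom so the calibration stage does
real work. `null_cohort_config()` zeroes effects and/or all variability for
null-hypothesis simulation and exact-recovery testing.

**What passing tests on this generator does not show.** The generator's
measurement model is exactly the model the fitters invert, with idealized
noise: it contains no layered or heterogeneous tissue (no scalp/skull/CSF
partial-volume effects), no motion or contact artifacts, no correlated
photon-counting noise on $g_2$ (the per-bin Gaussian with flat σ is a
simplification; correlation-noise models vary with lag and count rate), no
spatial correlation between nearby probe repositionings, and no inaccuracy
in the extinction table. Recovery results therefore validate the inverse
machinery and the statistical stage — not the adequacy of the semi-infinite
homogeneous model for real neonatal heads.

## Group statistics

The statistics stage mirrors the study design: linear mixed-effects models
(lme4/lmerTest) with sex as fixed effect and random intercepts for subject,
hemisphere side and lobe (`lme_sex_contrast()`), a gestational-age slope
with subject, side, lobe and sex as random intercepts (`lme_ga_trend()`),
Pearson correlations on subject means (`pearson_ga()`), Welch t-tests on
demographics, median aggregation across probe repetitions
(`aggregate_repetitions()` — the median matches the chain's robustness
conventions elsewhere), and the hemispheric percent difference computed as
$100(\bar{x}_R-\bar{x}_L)/\bar{x}_L$ on cohort means of subject-level side
means.

Two design decisions deserve explanation:

* *Random-effects structure.* "Side" and "lobe" have only 2–3 levels, so
  their variance components are frequently estimated at zero, which lme4
  reports as a singular fit. Singularity here is an expected boundary
  estimate, not a failure: discarding such fits would discard nearly every
  analysis. The functions therefore keep the estimate and flag
  `singular = TRUE`; the t-test-on-subject-means fallback engages only when
  the solver fails outright (and says so in the result and a warning).
* *p-values* come from lmerTest's Satterthwaite approximation. On degenerate
  zero-residual data (possible only in noise-free simulation) the
  approximation returns an uninformative p; estimates remain exact and are
  what the noise-free tests assert.

Type-I error of both mixed-model contrasts is verified by simulation: on
500 null cohorts at the study's size, the rejection rate at α = 0.05 must
lie inside the binomial 95% interval (an acceptance test). No
multiple-testing correction is applied across the parameter × region grid,
mirroring the study's analysis; interpret per-cell p-values accordingly.

## Problem sizes and determinism

All randomness flows from explicit integer seeds (`cohort_config(seed=)`,
`run_config(seed=)`); seeded runs are bit-reproducible, which the tests
assert. The test suite exercises full-size cohorts (30 subjects × 7 sites ×
3 repetitions with complete raw data) where the property under test needs
them — hemispheric-effect recovery uses 20 such cohorts, and the type-I
calibration uses 500 truth-level replicates — and small cohorts or reduced
sample counts where only the plumbing is under test; these sizes are stated
in the tests themselves.

## Known limitations

* Semi-infinite homogeneous medium throughout; no layered models, no
  Monte-Carlo photon transport, and a single reflection-geometry probe row.
* The DCS noise model is per-bin Gaussian; a count-rate-dependent
  correlation-noise model would be a pluggable extension.
* Single-exponential Brownian dynamics only; no multi-layer or
  ballistic-flow DCS variants.
* The extinction fixture is an interpolated transcription adequate for
  synthetic work; applications to real spectra should substitute a
  laboratory-grade table via `extinction_table(path=)`.
* Absolute CMRO2 requires a user-supplied blood hemoglobin concentration.
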