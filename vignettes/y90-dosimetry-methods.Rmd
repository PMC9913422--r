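---
title: "Voxel dosimetry and outcome modelling for Y-90 radioembolization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel dosimetry and outcome modelling for Y-90 radioembolization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taredose)
```

## The problem

In transarterial radioembolization (TARE), yttrium-90 microspheres are
delivered into hepatic arteries feeding liver tumours. Y-90 is a pure beta
emitter (half-life 2.67 days, mean beta energy 0.93 MeV, maximum 2.26 MeV,
soft-tissue range up to ~11 mm), so essentially all of the administered
activity decays in place and its energy is absorbed locally. The delivered
microsphere distribution can be imaged with post-treatment bremsstrahlung
SPECT/CT, which makes *post-hoc* three-dimensional dosimetry possible: how
much of the tumour actually received a tumoricidal dose, and where are the
under-dosed ("cold") regions that predict recurrence?

`taredose` implements that pipeline end to end on voxel grids: activity
calibration, two dose engines, dose-volume-histogram (DVH) metrics,
cold-spot detection with a retreatment-surveillance trigger, activity
prescription (MIRD and BSA), and the statistical cascade used to associate
dosimetric features with response, toxicity and survival. Because clinical
imaging and outcomes are protected data, the package ships a synthetic
phantom and cohort generator with retained ground truth; every stage can be
validated against known truth.

## Dose engines

Both engines start from an activity map $A_v$ (GBq per voxel), obtained by
scaling a counts map so that the field-of-view total equals the
administered activity net of the lung shunt fraction (and optionally a
residual vial fraction). Counts-to-activity proportionality is preserved
voxelwise; whether normalization is over the whole field or per structure
is a configuration choice, defaulting to whole field.

The energy released by complete decay of 1 GBq is
$$\Delta = 10^9 \cdot \frac{T_{1/2}}{\ln 2} \cdot \bar E \cdot 1.602\times10^{-13}
 \;\; \mathrm{Gy\,kg\,GBq^{-1}},$$
which evaluates to ≈ 49.6 Gy·kg/GBq for $T_{1/2} = 2.67$ d and
$\bar E = 0.93$ MeV. The dose engine uses this derived value by default;
prescription calculations default to the conventional rounded 50. Both are
configurable, and `physics_constants()` recomputes and asserts the derived
value unless explicitly overridden.

**Local Deposition Model (LDM).** Each voxel's activity deposits all its
energy in that voxel:
$D_v = \Delta A_v / (\rho \, V_{\mathrm{vox}})$, with uniform soft-tissue
density $\rho = 1.03$ g/cc (liver is near-uniform; no CT density map is
used).

**Dose-point-kernel (DPK) convolution.** The voxel energy field
$\Delta A_v$ is convolved with a normalized spreading kernel and divided by
voxel mass. Kernels are discretized on the voxel lattice and renormalized
to unit sum (all emitted energy deposited within support). Three kinds are
supported: `delta` (reproduces LDM bit for bit), `gaussian_dpk`, and
`tabulated_dpk`, a plain-text radial table. The shipped table
(`inst/extdata/y90_dpk_synthetic.tsv`) is an analytic stand-in — a smooth
monotone profile cut off at the 11.3 mm Y-90 maximum range — labelled
synthetic; it is not a Monte-Carlo transport result, and its role is to
provide a realistic short-range kernel so the two engines constitute
genuinely different implementations. Convolution is FFT-based with zero
padding; energy conservation is therefore asserted only for sources at
least one kernel support away from the grid edge, where it holds to 0.1%.

## DVH metrics

All headline metrics are computed on exact sorted voxel doses, not on a
binned curve: with $n$ structure voxels, $D_x$ is the
$\lceil nx/100 \rceil$-th largest voxel dose — the largest dose $d$ such
that the fraction receiving at least $d$ reaches $x\%$. The binned
cumulative DVH (default 0.5 Gy bins) exists for export and plotting only.
"Receiving less than" a threshold is strict (`<`); "receiving at least" the
reference isodose in the conformity indices is inclusive (`>=`). The
conformity index CI counts *any* imaged voxel at or above the 120 Gy
reference; the healthy-tissue overdose factor HTOF restricts to
liver-minus-GTV — the two formulas deliberately name different volumes.
The reference isodose is 120 Gy (the glass-sphere prescription level)
regardless of sphere type, with a configuration key for 85 Gy resin
analyses. The heterogeneity index HI = D5/D95 is ≥ 1 whenever D95 > 0
under this definition and is flagged `NA` at D95 = 0; reported clinical HI
values below 1 are not reproducible under the printed formula and are not
attempted.

Cold spots are the connected components of {GTV voxel : dose < 100 Gy}
under 26-neighbour connectivity. The surveillance trigger uses the *total*
cold volume (strictly greater than 20 cc), matching the published
retreatment rule; per-component volumes and centroids are reported for
localization because it is clinically unresolved whether scattered cold
spots carry the same significance as a single large one.

## Prescription

Glass spheres use the single-compartment MIRD relation
$A = D\,M / (\Delta_{rx}(1-\mathrm{LSF})(1-\mathrm{residual}))$ with a
120 Gy default prescription; the multi-compartment partition model with
separately measured uptake ratios is out of scope, and the implementation
is labelled single-compartment. Resin spheres use the empirical BSA method
$A = (\mathrm{BSA} - 0.2) + V_t/(V_t + V_n)$ GBq with stepped lung-shunt
reductions (×1.0 below 10%, ×0.8 for 10–15%, ×0.6 for 15–20%) and a hard
contraindication error above 20%; the tumour-fraction denominator is total
liver, the common published form. BSA comes from the Du Bois formula when
height and weight are given. A closure property ties prescription to the
dose engine: activity prescribed for a mass, spread uniformly over it, and
pushed through the LDM returns the prescribed dose within 1% when the same
$\Delta$ is used on both sides.

## Synthetic data

**Phantoms.** The anatomy is an ellipsoidal liver (axis ratios 1 : 0.8 :
0.6) sized to the requested volume, with spherical tumours (each with its
own tumour-to-normal uptake ratio, enforced to lie inside the liver) that
may contain spherical cold regions (uptake multiplier in [0, 1)). The
default grid mirrors the clinical acquisition: 128 × 128 in-plane at
4.8 mm with 3.0 mm slices. The imaging chain is emulated as a normalized
Gaussian blur (default 9.0 mm FWHM, the clinical reconstruction
pre-filter) followed by Gaussian noise with variance proportional to the
blurred signal — a standard approximation to Poisson statistics at SPECT
count levels, chosen because it is parameter-recoverable; collimator
response, attenuation, scatter and OSEM reconstruction are deliberately
not modelled. Passing tests on these phantoms therefore demonstrates
correctness of the dosimetry pipeline, not fidelity of any reconstruction
physics: real bremsstrahlung maps are noisier and less quantitative than
anything the generator produces.

**Cohorts.** Each synthetic treatment's intratumoral dose distribution is
modelled lognormal$(\mu_i, \sigma_i)$, which makes the whole Dx family,
the sub-threshold volumes, HI and the cold volume mutually consistent
closed forms of two parameters. Outcomes are generated with the
directional structure the analysis assumes: objective response is
logistic in the cold volume (default $\beta_0 = 1.4$,
$\beta_{\mathrm{cold}} = -0.015$ per cc), grade ≥ 3 toxicity is logistic
in baseline bilirubin and mean nontumorous-liver dose, and OS/PFS are
exponential proportional hazards in response status and cold volume,
calibrated so responder/non-responder medians land near 22.5/7.6 months
(OS) and 13.1/4.7 months (PFS). These defaults are a calibration chosen to
emulate reported lobar-TARE summaries — they are not ground truth about
any population, and the generator labels them as such by retaining every
latent quantity (`true_p_response`, `true_os_hazard`, ...) in the output
for recovery testing. Censoring is generated by censoring each record with
the requested probability at a uniform fraction of its event time, which
gives the exact expected censoring rate and guarantees that a rate of zero
yields all events.

## Statistical cascade

Features enter multivariate analysis through a univariate screen at
p ≤ 0.20 — single-predictor logistic regression for dichotomous outcomes,
single-covariate Cox for time-to-event. Screen p-values are
likelihood-ratio based: Wald p-values degenerate toward 1 under complete
separation (the Hauck–Donner effect), which would absurdly screen *out* a
perfectly separating feature. Constant features are excluded with a
warning. Before the multivariate logistic fit, pairwise |r| > 0.9 features
are pruned (later-listed dropped, reported): the Dx metrics are
near-duplicates by construction. Quasi-separation is detected as a
diverging estimate with an exploding standard error and reported as an
error, never silently.

Cox models use Efron tie handling. Kaplan–Meier medians are the first time
the curve reaches 0.5 or below (undefined if never); the log-rank test is
two-group, unstratified, two-sided. One-way ANOVA is the classical F test;
Fisher LSD pairwise comparisons use the pooled within-group variance, and
the one-sided option (used for directional dose comparisons such as
responders receiving more than non-responders) halves the two-sided p when
the observed difference lies in the hypothesized direction and takes the
complement otherwise. ROC curves are built over all observed thresholds
and integrated trapezoidally, which equals the Mann–Whitney U statistic
over $n_1 n_0$ with ties counted one half; the direction is auto-oriented
so the reported AUC is ≥ 0.5, with the orientation recorded. Split-dose
same-day treatments are handled by the cohort's row structure: response
rows per target, toxicity per session.

## Validation design and problem sizes

The package validates itself in layers: exact oracles (brute-force Dx
scans, closed-form 2×2 logistic coefficients, U-statistic AUC), physical
invariants (energy conservation to 0.1% for interior sources, exact
linearity, prescription closure within 1%), recovery experiments
(logistic CI coverage of the generator's $\beta_{\mathrm{cold}}$, Cox
recovery of a known hazard ratio of 2), and a two-engine agreement study:
51 seeded synthetic treatments are pushed through both engines and the
per-metric Pearson correlation across cases (GTV max, mean, D95, D70,
D50, D2) is required to exceed 0.96 for every metric — the level at which
independent commercial voxel-dosimetry platforms are considered
interchangeable. The agreement study runs on 72 × 72 × 48 grids at the
clinical 4.8 × 4.8 × 3.0 mm spacing — a field of view cropped around the
liver, chosen as a deliberate problem-size trade-off that leaves voxel
size, blur and noise at their clinical values.

```{r agreement, eval = FALSE}
study <- engine_agreement_study(n_cases = 51, seed = 1)
study$correlations
study$min_correlation
```

## Numerical choices and degenerate inputs

* FFT convolution pads to fast composite sizes and clamps round-off
  negatives (below $10^{-12}$ of the maximum) to zero.
* Kernel discretization samples the radial table at voxel-centre radii and
  renormalizes to unit sum (asserted to $10^{-6}$).
* Masks resampled between grids use exact separable interval-overlap
  fractions with a majority (0.5) inclusion default — symmetric and
  volume-preserving in expectation; how clinical software resamples
  contours is generally undocumented, so this is a declared choice.
* Empty masks, zero counts, zero administered activity, all-censored
  cohorts, and single-class outcomes are hard errors with specific
  messages; spacing metadata is never defaulted.
* All simulators save and restore the caller's RNG state; the same seed
  reproduces phantoms and cohorts bit for bit.

## Known limitations

* The dose engines assume complete decay in situ and uniform density; no
  biologically effective dose conversion.
* The synthetic kernel is a plausibility stand-in; absolute DPK dose
  profiles should not be quoted against published Monte-Carlo kernels.
* The phantom imaging model omits attenuation, scatter, collimator
  response and reconstruction; quantitative biases of real bremsstrahlung
  SPECT are therefore not represented.
* The cohort generator's effect sizes are calibrated, not estimated from
  data; analyses of it demonstrate statistical machinery, not clinical
  effect sizes.
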