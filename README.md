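# taredose

Voxel dosimetry and outcome analysis for yttrium-90 transarterial
radioembolization (TARE) of hepatocellular carcinoma.

After TARE, the delivered Y-90 microsphere distribution can be imaged with
bremsstrahlung SPECT/CT and converted into a three-dimensional absorbed-dose
map. What predicts treatment response is not the mean or median tumour dose
but volumetric *coverage*: how much gross tumour volume (GTV) fell below a
tumoricidal threshold, and where the under-dosed cold spots are. `taredose`
is for medical physicists and imaging scientists who want that analysis as
reusable, tested code: dose engines, DVH metrics, cold-spot detection with a
retreatment-surveillance trigger, activity prescription, and the outcome
statistics layer — plus a synthetic phantom and cohort generator with
retained ground truth, so the whole pipeline is verifiable without patient
data.

## What it computes

**Dose engines.** A counts volume is calibrated so its total equals the
administered activity net of the lung shunt fraction (1 mCi = 0.037 GBq),
then converted to dose either by the Local Deposition Model,

D_v = Δ·A_v / (ρ·V_vox),  Δ = 10⁹·(T₁ᵢ₂/ln 2)·Ē·1.602×10⁻¹³ ≈ 49.6 Gy·kg/GBq,

or by convolving the voxel energy field with a normalized dose-point kernel
(a delta kernel reproduces the LDM exactly; a synthetic Y-90-like radial
table ships with the package).

**Metrics.** Dx (minimum dose covering the hottest x% of the GTV, computed
on exact sorted voxel doses) for x ∈ {2, 5, 50, 70, 95, 98}; GTV volumes
below 120/100/70/50 Gy; heterogeneity index HI = D5/D95; conformity index
CI = (tissue ≥ 120 Gy)/GTV; healthy-tissue overdose factor
HTOF = (nontumorous liver ≥ 120 Gy)/GTV; activity density; disease burden.
Cold spots are 26-connected components of GTV voxels under 100 Gy; a total
cold volume above 20 cc raises the early-surveillance trigger.

**Prescription.** Single-compartment MIRD activity for glass spheres
(120 Gy default), the BSA method with stepped lung-shunt reductions for
resin spheres (contraindicated above 20% shunt), Du Bois body surface area.

**Statistics.** Best mRECIST response over a follow-up series; univariate
screening at p ≤ 0.20 into multivariate logistic or Cox models (Efron
ties); Kaplan–Meier with log-rank; one-way ANOVA with Fisher LSD
(optionally one-sided); trapezoidal ROC AUC (equal to the Mann–Whitney
statistic, ties counted ½).

## Worked example

```r
library(taredose)

spec <- phantom_spec(
  liver_volume_cc = 1500,
  tumors = list(list(center_mm = c(0, 0, 0), radius_mm = 20,
                     uptake_ratio = 4)),
  cold_spots = list(list(center_mm = c(8, 0, 0), radius_mm = 8,
                         multiplier = 0.1)),
  grid_dim = c(48, 48, 40), seed = 7)

ph   <- simulate_phantom(spec, total_activity_GBq = 1.45)
act  <- calibrate_activity(ph$counts, administered_activity_mCi = 39.25,
                           lsf = 0.05)
dose <- ldm_dose(act)

summary_metrics(dose, ph$gtv, ph$liver, administered_activity_mCi = 39.25)
#> <dose_metrics> GTV 34.84 cc, liver 1502 cc, burden 0.023
#>   GTV dose Gy: min 59.6  median 130.5  mean 129.9  max 164.8
#>   D2 163.8  D5 162.0  D50 130.5  D70 116.8  D95 101.5  D98 84.8
#>   V<120 13.8  V<100 1.5  V<70 0.3  V<50 0.0 cc
#>   HI 1.60  CI 0.603  HTOF 0.000  activity density 37.39 cc/mCi
#>   mean nontumorous-liver dose 39.4 Gy

cold_spot_components(dose, ph$gtv)
#> <cold_spot_report> 2 component(s), total 1.45 cc below 100 Gy
#>   early-surveillance trigger (> 20 cc): not raised
```

Reading the output: the 34.8 cc tumour received a median dose of 130 Gy,
above the 120 Gy prescription level, but coverage is imperfect — 1.5 cc of
tumour sits below 100 Gy (the deliberately under-perfused region of the
phantom, largely filled in by the 9 mm imaging blur). Because the total
cold volume is under 20 cc, the retreatment-surveillance trigger stays
down. HI = 1.60 indicates moderate intratumoral heterogeneity; HTOF = 0
means no nontumorous liver reached 120 Gy.

On a simulated cohort, the statistics layer runs the same cascade used for
clinical association studies:

```r
cohort <- simulate_cohort(cohort_gen_params(n_treatments = 200, seed = 1))
scr <- univariate_screen(cohort, c("v_lt_100_cc", "d70_gy", "hi", "burden"),
                         outcome = "objective_response")
logistic_mva(cohort, scr$feature[scr$selected], "objective_response")
km_logrank(cohort$os_months, cohort$os_event,
           ifelse(cohort$objective_response, "responder", "non-responder"))
```

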