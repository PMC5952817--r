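# cmrperf

Quantitative stress-perfusion cardiac magnetic resonance (CMR): myocardial
blood flow by Fermi-constrained deconvolution, ischemic burden on the
32-sub-segment AHA model, composite-endpoint adjudication, and
cross-validated penalized-Cox prognostic modelling — with a synthetic-data
module that stands in for patient data, so the whole pipeline is testable
end to end.

## The problem

Stress perfusion CMR is usually read visually. Quantitative analysis
instead estimates myocardial blood flow (MBF) per segment from the
first-pass signal curves and summarises ischemia as a *burden* — the
fraction of left-ventricular myocardium with impaired perfusion reserve.
This package implements the full analysis chain needed to ask whether that
quantitative burden adds prognostic value over established risk factors
(age, sex, late gadolinium enhancement), and whether the consensus
thresholds (≥2 abnormal segments, ≥10% of myocardium) carry over to CMR:

1. **Dual-bolus AIF correction.** The arterial input function (AIF) is
   measured from a 1:10 dilute pre-bolus (0.0075 mmol/kg) whose signal is
   still linear, then scaled by the dose ratio to stand in for the
   saturated full-dose AIF.
2. **Fermi-constrained deconvolution.** The tissue curve is modelled as
   the convolution of the AIF with a Fermi impulse response
   `h(t) = R·[1/(e^{(t−τ₀−τ_d)k}+1)]·u(t−τ_d)`; `R`, `k`, `τ₀` are fitted
   by Marquardt–Levenberg least squares with `τ_d` fixed, and
   MBF = `R/(e^{−τ₀k}+1)`, the delay-aligned amplitude of `h`. The
   myocardial perfusion reserve (MPR) is stress MBF / rest MBF; a
   sub-segment with MPR < 1.5 is ischemic.
3. **Ischemic burden.** Each of the 16 AHA segments is split into
   endocardial/epicardial halves (32 sub-segments); burden is the
   mass-weighted ischemic fraction, with LGE (scar) sub-segments excluded
   from assessment. Dichotomization: visual ischemia in ≥2 AHA segments,
   quantitative burden ≥10%.
4. **Outcomes.** Composite endpoint (cardiovascular death, nonfatal MI,
   aborted sudden cardiac death, late revascularization), with
   revascularizations within 90 days of the scan blanked and only the
   first qualifying event counted.
5. **Prognosis.** L1-penalized Cox models (age/sex/LGE unpenalized, the
   perfusion covariate penalized), double-loop cross-validation for
   out-of-fold 2-year event probabilities, time-dependent ROC/AUC with
   censoring weights, guideline risk categories (<1%, 1–3%, >3%), and
   categorical net reclassification improvement (NRI) / integrated
   discrimination improvement (IDI) against the baseline model.

## Worked example

Simulate one dual-bolus acquisition with a known ground-truth flow and
recover it:

```r
library(cmrperf)

spec  <- acquisition_spec()                         # 60 frames, 1 s apart
truth <- list(`7_endo` = tissue_truth(2.0, k = 0.25, tau0 = 3, taud = 2),
              `7_epi`  = tissue_truth(3.0, k = 0.20, tau0 = 4, taud = 2))
study <- generate_dual_bolus_study(spec, truth, seed = 1)
quantify_perfusion(study$curves)
#>   patient_id region  phase taud mbf          rss converged
#> 1       P001 7_endo stress    2   2 1.467769e-28      TRUE
#> 2       P001  7_epi stress    2   3 2.813508e-28      TRUE
```

The noiseless curves deconvolve back to the generating flows (2.0 and 3.0
relative units) exactly. The numbered scripts under `analysis/` run the
same machinery at cohort scale — `01_simulate_data.R` through
`05_prognosis.R` — writing tables under `results/`; on the default
synthetic cohort of 2000 patients the cross-validated 2-year AUC rises
from 0.738 (baseline age/sex/LGE model) to 0.761 when the quantitative
burden is added, with the dichotomized (≥10%) variant at 0.747.

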