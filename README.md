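# lpmadc

Linear Poisson Modelling (LPM) of apparent-diffusion-coefficient (ADC)
histograms, for detecting and quantifying treatment response in **individual
tumors** from diffusion-weighted MRI.

## The problem

Preclinical imaging studies compare treated and control tumor cohorts with
t-tests on summary parameters (mean ADC, 95th percentile, volume). Tumors are
spatially heterogeneous — they contain multiple *habitats* (viable tissue,
necrosis, treatment-induced necrosis) whose voxel-value distributions overlap
and drift with natural-history growth. Summaries discard that structure, so
subtle or partial responses vanish into between-tumor variance and only
cohort-level effects are detectable, and only with large groups.

`lpmadc` instead models each tumor's multi-visit ADC histogram bin-by-bin.
With `A` an ADC bin and `V` a visit, a tumor's histogram is described as a
non-negative mixture of learned probability-mass-function components with
Poisson bin noise:

    H(A,V) ≈ M(A,V|C=c) + M(A,V|C=t)
    M(A,V|C=c) = Σ_c P(A,V|C=c) Q_c      (control/natural-history habitats)
    M(A,V|C=t) = Σ_t P(A,V|C=t) Q_t      (treatment-specific habitats)

Training is two-stage: the control components are learned from a control
cohort (EM with random restarts, leave-one-out model-order selection and
chi-square sufficiency checks), then frozen while additional
treatment-labelled components are learned from the treated cohort, so that
treatment components describe only behaviour absent from controls. For each
tumor the treatment-attributed voxel count `QT = Σ_t Q_t` is a lower bound on
the volume affected by therapy; its standard error σ follows from the
observed Fisher information of the extended Poisson likelihood, giving a
per-tumor Z-score `Z = QT/σ` (Z > 3 calls a responder) and p-value.

Two power calculations support study design:

* voxel-count power: `Z = sqrt(Q_total · (T* − (1 − T* − C*)² / (4 C*)))`,
  where the ambiguity terms T*, C* measure the overlap between control and
  treated distributions;
* cohort size: the probability of seeing at least one responder among N
  tumors when a fraction F respond, `P = 1 − (1 − F)^N`, and the smallest N
  reaching a target confidence.

A Monte Carlo simulator synthesizes cohorts from fitted tumor pairs and
compares the true/false positive rates of per-tumor LPM detection against
conventional t-tests across significance thresholds, and a synthetic-data
module generates multi-habitat studies with known ground truth so the whole
pipeline is testable without any imaging data.

## Worked example

A synthetic radiotherapy study under the default conditions (15 control and
9 treated tumors, 2000 voxels per tumor, visits V1/V2):

```r
library(lpmadc)
study <- sample_study(make_truth_model(truth_config()), seed = 1)
ctrl <- dplyr::filter(study$histograms, cohort == "control")
trt  <- dplyr::filter(study$histograms, cohort == "treated")

st <- lpm_settings(restarts = 8, max_iter = 800, tol = 1e-7)
control_model <- lpm_train_control(ctrl, k_range = 1:6, settings = st, seed = 2)
full_model <- lpm_add_treatment(control_model, trt, k_range = 0:3, settings = st, seed = 3)
glance(full_model)
#>   k_total k_control k_treatment  loglik fit_value sufficient  seed
#> 1       4         3           1 133854.      1.09 FALSE          3

assessment <- lpm_assess(trt, full_model, voxel_vol = 0.25, settings = st)
dplyr::select(assessment, tumor_id, q_treatment, sigma, z, responder, affected_volume_mm3)
#>   tumor_id q_treatment sigma     z responder affected_volume_mm3
#> 1 T01            1179.  34.7  33.9 TRUE                     295.
#> 2 T02             972.  31.5  30.9 TRUE                     243.
#> 3 T03             780.  28.1  27.8 TRUE                     195.
#> ...
```

Leave-one-out selection settles on 3 control components plus 1 treatment
component, with a held-out fit value (√(χ²/d.f.)) of 1.09. Every treated
tumor is individually flagged (Z ≫ 3) with 600–1200 treatment-attributed
voxels — 30–60% of each tumor — and, at the Calu6 voxel geometry
(0.25 mm³/voxel), affected volumes of 160–300 mm³. The `sufficient = FALSE`
flag here is the conservative Bland–Altman residual screen tripping on a
residual-mean threshold; the selection curves and fit value in
`full_model$meta` show a well-specified model (see the vignette).

Power queries use the same objects:

```r
amb <- ambiguity_terms(full_model, assessment$fit)
#>   t_star c_star
#> 1  0.980  0.996
predict_z(2000, amb = amb)         # 38.5 — attainable Z at 2000 voxels
detection_probability(5, 0.5)      # 0.96875
min_cohort_for_confidence(0.5, 0.95)  # 5
```

So with half of tumors responding, a treatment cohort of five suffices for a
>95% chance of at least one detected responder — the small-N design this
method exists to enable.

A thin command-line wrapper over the same functions is installed at
`inst/cli/lpm.R` (subcommands `synthesize`, `fit-control`, `fit-treatment`,
`assess`, `simulate-cohorts`, `power-z`, `power-cohort`).

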