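---
title: "Methods: dose-volume toxicity modeling with bootstrap LASSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-volume toxicity modeling with bootstrap LASSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modeling problem

Radiation pneumonitis and esophagitis are the dose-limiting toxicities of
thoracic radiotherapy. The standard modeling substrate is the cumulative
dose-volume histogram (DVH): for every dose level $D$, the fraction $V(D)$
of a structure's volume receiving at least $D$. `ntcplasso` implements a
complete normal-tissue-complication-probability (NTCP) workflow on this
substrate:

1. **EQD2 conversion.** Plans with different fraction sizes are made
   comparable through the linear-quadratic equivalent dose in 2 Gy
   fractions, $\mathrm{EQD2} = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta}$,
   with per-bin fraction size $d = D/n_{\mathrm{fx}}$ and tissue ratio
   $\alpha/\beta$ (10 Gy for acutely responding esophagus, 3 Gy for
   late-responding lung-minus-GTV and heart).
2. **Feature extraction.** The $D_x$ grid ($x = 5\%$ to $100\%$ in 5%
   steps: minimum dose to the hottest $x\%$ of the volume), mean and
   maximum dose, and for the esophagus the "fractional" set $fD_x = D_x /
   \text{treatment days}$ (Gy/day), capturing daily dose intensity for an
   acutely developing endpoint.
3. **Univariate screening.** Spearman rank correlation of every feature
   against the *ordinal* CTCAE grade (0–5), not the dichotomized endpoint,
   plus a Wilcoxon rank-sum comparison between the grade $<2$ and $\ge 2$
   groups. Features with Spearman $p < 0.1$ proceed; treatment days, the
   SBRT flag and chemotherapy are always carried forward. No
   multiple-testing correction is applied at this stage — the screen is a
   candidate filter, not an inferential claim.
4. **Collinearity reduction.** Adjacent $D_x$ values are nearly collinear.
   Average-linkage hierarchical clustering on the distance $1 - |r|$
   (Pearson), cut so that clusters correspond to correlations above 0.75,
   followed by keeping per cluster the variable best correlated (largest
   $|r_s|$) with the endpoint.
5. **Stability selection.** A stratified 2/3–1/3 train/validation split
   balanced on cancer subtype and outcome; then 1,000 bootstrap resamples
   of the training set, each fitted with LASSO logistic regression and
   scored on the fixed validation set (Mann–Whitney AUC). Feature selection
   frequencies and pairwise co-selection counts summarize stability.
6. **Final model and calibration.** One LASSO fit on the full training
   data, reported as coefficient / bootstrap SD / odds ratio
   $e^{\beta}$ / 95% percentile CI, and a six-bin observed-vs-predicted
   calibration table on the validation set.

# Numerical conventions

* **$D_x$ interpolation** is linear in dose between cumulative-DVH bins.
  Flat plateaus below $V = 1$ resolve to the *lowest* dose achieving the
  target fraction ("minimum dose to the volume"); $D_{100}$ is the end of
  the leading $V = 1$ plateau, i.e. the minimum structure dose. Input
  curves are resampled to a uniform 0.1 Gy grid *before* the EQD2
  transform — transforming a coarse curve first and interpolating
  afterwards would lose the transform's curvature.
* **Mean dose** is the trapezoidal integral of the cumulative curve, which
  for a curve falling to zero equals the differential-DVH weighted mean
  exactly (integration by parts).
* **Max dose** is the highest bin edge with $V > 0$; no half-bin offset is
  added.
* **Fractional metrics** divide the *physical*-dose metrics by treatment
  days by default. Whether the reference analysis divided physical or
  EQD2 dose is not documented anywhere we could find; both are supported
  (`fractional_basis`), physical is the default because the fractional
  variables model daily delivered intensity.
* **Wilcoxon rank-sum** uses mid-ranks; the two-sided $p$ is exact (full
  enumeration, doubled smaller tail, capped at 1) for $n \le 12$ without
  ties, otherwise a tie-corrected normal approximation with continuity
  correction.
* **Spearman $p$** uses the $t$-approximation with $n-2$ degrees of
  freedom; a seeded permutation alternative exists for validation. Binary
  covariates enter as 0/1 numerics (rank-biserial equivalent); smoking
  status is encoded both ordinally (never < former < current) and as
  ever/never.
* **LASSO.** Predictors are standardized with training-set statistics only
  (a shared penalty is meaningless otherwise); the penalty weight defaults
  to the 5-fold cross-validated deviance minimum with seeded folds,
  re-chosen within every bootstrap replicate; coefficients are reported on
  the original scale; "selected" means $|\beta| > 10^{-8}$. At
  $\lambda = 0$ the fit agrees with a Newton–Raphson maximum-likelihood
  oracle to $10^{-4}$ (tested). Bootstrap resamples with fewer than two
  observations of either outcome class are redrawn, keeping the replicate
  count fixed; the redraw count is reported.
* **Uncertainty for the final model.** A penalized fit has no standard
  closed-form SE; the table reports the bootstrap SD of each coefficient
  (zeros included) and the 2.5th/97.5th bootstrap percentiles mapped
  through $\exp$. This is a convention choice, documented rather than
  hidden.
* **Calibration bins** sort stably by predicted risk (ties by patient id)
  into six contiguous bins; when the validation size is not divisible by
  six, the extra patients go to the highest-risk bins. Predicted incidence
  per bin is the mean predicted probability, not the bin midpoint.
* **Seeds.** A single master seed deterministically derives one seed per
  stochastic stage; every sampling function consumes R's global stream
  under a saved-and-restored state, so identical configuration yields
  byte-identical artifacts and the caller's RNG is never perturbed.

# The synthetic cohort generator

No public dataset accompanies this class of analysis (institutional
cohorts are typically available only on request), so the package ships a
generator whose defaults state a fixed world resembling a 258-patient
thoracic RT cohort:

* **DVHs** follow a normalized logistic sigmoid in dose: midpoint
  $m = c \cdot \mathrm{Rx}$ (coverage fraction $c$, prescription
  $\mathrm{Rx}$), steepness scale $\mathrm{Rx}/k$, maximum dose
  $1.2\,\mathrm{Rx}$, with lognormal patient-level jitter on midpoint and
  steepness. Two parameters give realistic monotone falloff and — because
  neighbouring $D_x$ read the same sigmoid — the strong $D_x$
  collinearity the decorrelation stage assumes (adjacent-$D_x$ Pearson
  $r > 0.75$ is an asserted invariant). In the infinite-steepness,
  full-coverage limit the curve is a step at the prescription dose.
  For SBRT plans the coverage fraction is scaled down (default
  $\times 0.35$): tightly conformal few-fraction plans spare organs at
  risk far more than conventional fields, and without this scaling SBRT
  patients would carry *higher* organ-at-risk EQD2 (large fractions
  inflate EQD2), inverting the dose–toxicity alignment real cohorts show.
* **Fractionation** is a discrete menu: 60 Gy/30 fx/40 days and
  54 Gy/27 fx/37 days (conventional), 50 Gy/5 fx/10 days (SBRT), with
  probabilities 0.30/0.35/0.35 so the conventional and SBRT medians are
  54 and 50 Gy. Treatment days always cover the fraction count.
* **Clinical covariates**: age $\sim N(68, 10^2)$ truncated to 25–93;
  52.7% female; KPS peaked at 90; smoking never/former/current
  18.2/69.4/12.4%; pack-years lognormal (median 37) for ever-smokers;
  chemotherapy concurrent/sequential/none 23.2/28.7/48.1%; subtypes
  dominated by NSCLC (78.3%). Serum alpha-2-macroglobulin (A2M) is
  lognormal ($\sigma_{\log} = 0.34$) conditional on smoking, with
  multiplicative upward shifts for former and current smokers sized so
  group means track 185/207/217 mg/dL; the never-smoker location is
  anchored so the smoking-mixture median sits at 191 mg/dL. One lognormal
  family cannot hit the group means and the overall median simultaneously
  to the last digit; the compromise (both within a few percent) is
  deliberate and fixed.
* **Outcomes** come from a known logistic model over named features.
  The default esophagitis model loads esophagus $D_{50}$, treatment days,
  chemotherapy, A2M (protective) and age (protective); pneumonitis loads
  lung $D_{15}$, heart max dose, treatment days and female sex. When a
  target prevalence is configured instead of an explicit intercept
  (defaults: 23.6% esophagitis, 14.0% pneumonitis), the intercept is
  solved by `uniroot` so the mean event probability over the realized
  cohort equals the target — the prevalence is part of the stated world,
  so this calibration happens by construction, not by tuning. Events
  receive grade 2/3/4 and non-events grade 0/1 by configured splits
  (esophagitis events 53:8 grade 2:3; pneumonitis 26:9:1); only the
  Spearman stage uses the ordinal scale, everything else dichotomizes at
  grade $\ge 2$.
* **Independence assumptions.** A2M is generated independently of the
  dosimetric variables (no published estimate of that correlation exists);
  chemotherapy is independent of modality. Both are configurable; the
  defaults are flagged here precisely because real cohorts will violate
  them (SBRT patients rarely receive concurrent chemotherapy).

A green test against this generator establishes that the pipeline recovers
a known data-generating process of realistic shape, collinearity and
prevalence. It does **not** establish clinical validity, transportability
to real planning-system exports, or the published cohort's specific effect
estimates — the institutional data behind those are not public.

## The parameter-recovery world

The acceptance property uses a deliberately simplified variant: a single
conventional schedule (60 Gy/30 fx/40 days), two dosimetric drivers
(esophagus $D_{40}$, lung $D_{15}$; coefficients 0.4 and 0.45 per Gy,
sized to give oracle AUC near 0.8 — the discrimination regime reported for
models of this kind), six null features, 30% prevalence, $n = 600$. A
mixed conventional/SBRT menu would couple *all* structures through the
prescription dose and confound the driver-versus-null contrast the
property is about; fixing the schedule keeps drivers and nulls mutually
near-independent. With 200 bootstrap replicates, both drivers must be
selected more often than every null and the ensemble's mean validation
AUC must sit within 0.05 of the generating model's own AUC on the same
validation patients.

# Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `alpha_beta` | 10 (esophagus), 3 (lung, heart) | Gy | standard acute/late radiosensitivity ratios |
| `x_grid` | 5–100 by 5 | % | the conventional $D_x$ reporting grid |
| `bin_width` | 0.1 | Gy | resampling grid; removes planning-system dialects |
| `screening_alpha` | 0.1 | – | permissive candidate screen |
| `correlation_threshold` | 0.75 | – | collinearity cutoff for clustering |
| `linkage` | average | – | conventional for correlation-based variable clustering; complete available |
| `train_fraction` | 2/3 | – | stratified split |
| `n_boot` | 1000 | – | stability-selection replicates |
| `lambda_rule` | 5-fold CV deviance minimum | – | re-chosen per replicate; `fixed` available for speed |
| `exclude` | dose per fraction, fraction number | – | near-copies of treatment days, removed a priori |

# Known limitations

* The DVH generator produces smooth sigmoid curves; real DVHs can be
  multimodal (e.g. split target volumes) and the resampling step is the
  only defence against grid dialects.
* The fractional-variable basis (physical vs EQD2) and the heart max-dose
  conversion are under-documented in the reference analysis; defaults are
  stated above and switchable.
* Percentile bootstrap CIs around a sparse point estimate mix the
  selection event into the interval; with many zero replicates the
  interval can touch 1 exactly. This mirrors how stability selection is
  usually reported, but it is not a coverage-calibrated interval.
* No optimism correction beyond the fixed validation split; no
  time-to-event structure; no DICOM-RT import.
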