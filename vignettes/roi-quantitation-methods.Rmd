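---
title: "ROI quantitation of four-phase renal CT: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI quantitation of four-phase renal CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalroi)
```

# The clinical problem and the measurement model

Small (≤ 4 cm) renal masses are frequently found incidentally. Most
malignant ones are clear cell renal cell carcinomas (ccRCC); the most common
benign mimic is angiomyolipoma, and the fat-poor variant (AML.wovf) lacks
the macroscopic fat that normally gives angiomyolipoma away on CT. The two
differ systematically in *how much* they enhance after contrast and *how
evenly*: ccRCC tends to enhance strongly and heterogeneously in the
corticomedullary phase (CMP), AML.wovf more mildly and homogeneously.

`renalroi` quantifies both properties from plain ROI statistics:

* enhancement degree via the mean attenuation in a small ROI over the
  most-enhancing tissue — **AVT** — normalized either against the
  pre-contrast value (**NEV** = AVT − AVT_PCP, in HU) or against
  homogeneous adjacent renal cortex (**RER** = AVT/AVC × 100, in %);
* enhancement heterogeneity via the attenuation SD inside a whole-tumor ROI
  — **HDT** — normalized against the psoas SD at the same level
  (**SHR** = HDT/HDP × 100), which discounts scanner noise common to both
  regions.

Three ROI protocols are implemented. ROI (1) (50–100 mm²) and ROI (2)
(10–20 mm²) are placed on the richest-enhancing patch in CMP and propagated
unchanged to the other phases; ROI (3) covers the whole tumor on its
largest cross-section, fixed on the excretory phase where the boundary is
sharpest and propagated backwards. Averaging is a flat grand mean over
enhancement regions × three adjacent section-images × repeats × observers;
the per-level averages prescribed by the protocol are order-independent for
balanced layouts, so the flat mean is equivalent and simpler.

# The prediction models

For each phase a logistic model scores the probability that a lesion is
ccRCC (coded 1), combining gender (male = 1), one morphology flag
(present = 1) and the phase's quantitative parameters. The fixed published
coefficient sets are shipped as a versioned JSON resource
(`inst/extdata/published_models.json`) and exposed by `published_model()`;
`fit_logistic()` refits the same structure by maximum likelihood and
`screen_variables()` performs backward likelihood-ratio elimination at
α = 0.05 from the univariately significant candidate pool.

Three modelling choices were genuinely open and are fixed as follows:

* **Coding** male = 1, flag present = 1, ccRCC = 1. This is the only
  orientation under which the printed coefficient signs agree with the
  observed class compositions (males, pseudocapsule and cystic degeneration
  enriched in ccRCC; angular interface enriched in AML.wovf) *and* the
  fixed CMP model separates the two worked corticomedullary lesions
  correctly.
* **Classification threshold** 0.5, the standard logistic classification
  table; no other threshold is documented for the originals.
* **Screening algorithm** backward elimination with the likelihood-ratio
  test. The selection algorithm behind the published models is not named;
  forward or full-enter variants change only which correlated variable of a
  pair survives, and the direction is configurable in principle via the
  candidate pool.

A caution discovered while validating the published coefficient sets: in
the nephrographic-phase block, the printed odds-ratio column is internally
inconsistent with its own coefficients and Wald confidence intervals
(`exp(coef)` matches the geometric centre of the CI but not the printed OR
for three of four rows). `odds_ratio_consistency()` quantifies this; the
coefficients are treated as authoritative throughout.

# What the synthetic generators emulate

**Tabular cohorts** (`simulate_cohort()`). Each class draws its
quantitative parameters from normal distributions with the reference
per-class means/SDs (`cohort_reference()`), and its categoricals from the
reference frequencies; 74 ccRCC / 31 AML.wovf by default. Only marginal
summaries are published, so features are independent by default; a common
correlation is configurable because real CT parameters co-vary strongly.
Derived-parameter identities (e.g. NEV = AVT − AVT_PCP) hold only in
expectation here, since every column is drawn marginally — the voxel
pipeline, not the tabular simulator, is where those identities are exact.

**Voxel phantoms** (`simulate_lesion_volume()`). A spherical tumor on a
0.7 mm × 0.7 mm × 1 mm grid (the thin-slice protocol the measurements
assume) containing: compact enhancement patches near the margin, thin
arc-shaped vessels offset from the patch plane, central non-enhancing
cysts, an optional hypodense pseudocapsule rim, plus homogeneous cortex and
psoas reference slabs, all under i.i.d. Gaussian HU noise. Calibration was
fixed once, before any acceptance measurement:

* noise SD 9.6 HU — back-solved from the reference HDT_CMP/SHR_CMP pair
  (39.58 HU / 412 %), so the psoas SD lands at the value that makes SHR
  consistent;
* cortex HU per phase back-solved from the reference AVT(2)/RER(2) ratios
  (≈ 187 HU in CMP);
* patch HU = the per-class smaller-ROI attenuation means; bulk tumor HU =
  the whole-tumor attenuation means; per-lesion variation drawn from the
  class SDs (`lesion_spec_from_class()`);
* cyst fluid 35 HU, constant across phases. With the default cyst burden
  this places the phantom's whole-tumor SD near the reference values in
  every phase (≈ 10 HU pre-contrast, rising sharply in CMP) while keeping
  cysts non-enhancing by construction.

What the phantom does **not** model: CT physics (beam hardening,
reconstruction kernels, dose-dependent noise texture), infiltrative or
non-spherical growth, partial-volume fat, registration error between
phases, and intra-class texture beyond the patch/cyst/vessel geometry.
Passing phantom tests therefore demonstrates that the *measurement and
statistics machinery* is correct under the stated intensity model — not
that the pipeline generalizes to scanner data.

**Observer replicates** (`simulate_observer_measurements()`) add
independent Gaussian measurement noise per observer and repeat. The default
15 HU on attenuation-scale features yields ICC ≈ 0.9 against a
between-lesion SD of ≈ 45 HU, inside the 0.808–0.961 agreement band
reported for the reference readings.

# Statistical conventions and numerical choices

* **Chi-square** Pearson, *no* continuity correction — the convention that
  reproduces the printed categorical statistics exactly.
* **Two-sample t** pooled (equal-variance), df = n₁ + n₂ − 2; Welch does
  not reproduce the printed values. The summary-statistic path and the
  raw-sample path are algebraically identical and tested to machine
  precision. Group sizes 74/31 are used when re-deriving printed
  statistics; the header sizes printed alongside the quantitative table
  (57/28) are inconsistent with both the cohort and the statistics.
* **Normality screen** Lilliefors-corrected Kolmogorov–Smirnov
  (`nortest::lillie.test`), the behavior of mainstream packages when
  parameters are estimated; the flag at α = 0.05 dispatches t vs
  Mann–Whitney. The dispatch holds its type-I error (≈ 0.04–0.05 over 1000
  null cohorts).
* **Mann–Whitney** SPSS-style tie-corrected asymptotic Z without continuity
  correction; an exact enumeration mode exists for small samples.
* **ICC** two-way random effects, absolute agreement, single measures
  (ICC(2,1)) from the balanced two-way mean squares; degenerate inputs
  (< 2 observers, < 3 lesions, missing cells) are rejected rather than
  patched.
* **AUC** midrank Mann–Whitney AUC with Hanley–McNeil SE, CI clipped to
  [0, 1]; orientation auto-flips to ≥ 0.5 with the flip recorded. The
  identity AUC = U/(n₁n₂) is a tested invariant.
* **SD convention** population (divisor n) for the heterogeneity SD,
  matching workstation readouts; the sample convention is available and the
  difference is negligible at whole-tumor pixel counts.
* **ROI discretization** a pixel belongs to a circular ROI when its centre
  lies within the radius; fixed-area placement starts at the top of the
  requested range and shrinks in 1/20-pixel steps until the disc fits the
  support and its pixel area is inside the range, signalling
  `region-too-small` (with an inscribed-circle fallback for the pipeline)
  when the lower bound is unreachable. The whole-tumor ROI maximizes the
  boundary distance over mask pixels (brute-force distance to the 4-adjacent
  background), then subtracts the 2.5 mm margin — the midpoint of the
  2–3 mm placement rule.
* **Enhancement-region detection** voxels above the 90th within-tumor
  percentile in CMP, 6-connected components, minimum volume 10 mm³,
  vessel exclusion by principal-axis elongation > 3, plus a mean-excess
  rule (component mean ≥ threshold + 2 noise SDs) that rejects chance
  clusters of noise voxels; cyst/calcification masks are excluded outright.
  The threshold and elongation cut are configurable because the protocol
  describes these structures only qualitatively.

# Problem sizes and determinism

Simulation-backed checks use sizes chosen to make their Monte-Carlo error
small relative to the asserted margins: 200 calibrated cohorts for the
refit-model AUC ordering, 1000 null cohorts for the dispatch type-I error,
50 replicates at n = 1000 for selection consistency, and single phantoms
for the voxel-level recovery checks (each measured quantity averages tens
of voxels, so 3-SE bounds are a fraction of an HU). One global seed governs
every draw; per-lesion sub-seeds are derived deterministically from it, so
cohorts, phantoms and CLI outputs are bit-reproducible.

# Known limitations

* The phantom's heterogeneity is driven entirely by macroscopic structures
  plus white noise; textural heterogeneity (and hence absolute HDT levels
  for structure-poor lesions) is under-modelled.
* The tabular simulator's independence default understates the correlation
  between derived parameters sharing a numerator or denominator.
* Backward screening at α = 0.05 retains a chance noise variable in
  roughly one replicate in five when four noise candidates are offered —
  an inherent property of the selection level, not a defect; the retained
  true effects are stable.
* Morphology flags are simulated inputs; nothing in the package reads them
  from images, and tumor/organ masks are inputs to the measurement layer,
  not outputs of a segmenter.
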