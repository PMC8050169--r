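---
title: "Methods: from posture bouts to brain-network degree associations"
author: "stepconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from posture bouts to brain-network degree associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepconn)
```

## The scientific question

Cross-sectional cohort studies have linked objectively measured physical
activity and sedentary behaviour to structural properties of white-matter
brain networks. The analysis chain is long: thigh-worn accelerometer event
logs must be turned into daily-mean behaviour summaries; diffusion-MRI
streamline sets into individual weighted connectomes; group "reference
networks" define which connections are counted; and multivariable linear
models with nested confounder sets produce standardized effect estimates.
`stepconn` implements this chain as a tested, reusable pipeline, driven by
a synthetic cohort generator with known ground truth so that every stage —
and the pipeline end to end — can be validated without any cohort data.

## Accelerometer processing (`accel`)

The atom of input is the **event bout**: a contiguous period in one posture
(sit/lie, stand, step) with a step count. Processing follows the wear
protocol of an 8-day, 24 h/day thigh-worn device:

* **Valid days.** The first wear day is always excluded (device attachment
  and clinic testing). The final wear day is excluded when it provides 14
  or fewer waking hours. Remaining days are valid when they provide at
  least 10 waking hours; participants are retained with at least one valid
  day (a configurable minimum, kept at 1 by default because that is the
  protocol as published, lenient as it is).
* **Classification.** Sedentary posture is sedentary time (ST); standing is
  standing; stepping is split by cadence into high-intensity physical
  activity (HPA, strictly more than 110 steps/min) and low-intensity
  physical activity (LPA, at or below). Cadence is computed **per bout**
  (steps divided by bout duration): event-based monitors emit bouts, not
  epochs, and no epoching rule is part of the protocol. Because some
  cohorts epoch at one minute, the threshold and the classification entry
  point are exposed so an epoch-based front-end can reuse the rest of the
  chain; a per-second brute-force oracle in the test suite makes the
  per-bout choice auditable.
* **Waking windows.** Waking time determination is a separate algorithm in
  its own right; here wake windows are explicit inputs. Bouts straddling a
  window boundary are truncated at it with steps prorated by time, which
  leaves per-bout cadence unchanged — so a truncated HPA bout stays HPA.
* **Summaries.** Class minutes are summed within the wake windows of each
  valid day and averaged over valid days. By construction ST + standing +
  LPA + HPA equals waking time to within one second of accumulation per
  day, and LPA + HPA equals stepping time exactly.
* **Guideline stratum.** "High HPA" means meeting the 150 min/week
  guideline, i.e. at least 150/7 = 21.43 min/day, inclusive at the
  boundary.
* **Exposure inversion.** Because low activity is the hypothesised risk
  factor, PA exposures (total, LPA, HPA) are multiplied by −1 before
  modelling; sedentary time never is. Inversion flips the sign of a fitted
  standardized coefficient exactly, which the tests assert.

## Individual connectomes (`connectome`)

A streamline is assigned to the unordered pair of atlas regions containing
its first and last voxels ("from and to"); streamlines ending in
background, or starting and ending in the same region, are unassigned. A
pass-through mode (crediting every visited region pair) is available for
sensitivity analyses but is not the default. "Visited" means the polyline
vertex, rounded to the 2 mm diffusion grid — the grid the tract volume is
defined on; no supersampling or segment interpolation is attempted, and the
choice is oracle-tested.

The edge weight is the **tract volume**: the number of distinct voxels
visited by at least one streamline of that edge times the voxel volume
(8 mm³ at 2 mm isotropic). The union makes the weight idempotent under
duplicated streamlines. Weights are normalized to intracranial volume
(ICV), making them dimensionless and comparable across head sizes. Edges
supported by only one or two streamlines are removed from both matrices
(noise filter) before anything downstream — reference construction and
degree computation both see filtered networks, matching the position of the
filter at the end of preprocessing.

**Node degree is binary**: the count of incident edges, with weights used
only to decide edge existence (and to break reference-network ties). With a
120-region parcellation, published whole-brain degrees near 21 of a
possible 119 are consistent with this binarized reading. The whole-brain
value is the mean over all regions; regional values are means over the
member regions of each group. Sparsity is `1 − edges / (N(N−1)/2)`, so
sparsity + density = 1 exactly.

## Group reference networks (`refnet`)

For a comparison group, the per-edge **occurrence** is the number of
members whose filtered connectome contains the edge. Proportional
thresholding to sparsity 0.80 retains the 20% of all possible edges with
the highest occurrence (1428 of 7140 for N = 120). Ties at the cutoff are
broken by higher group-mean weight, then lexicographically by `(i, j)`:
no tie rule is part of the published description, and determinism —
including invariance to participant ordering — is non-negotiable for a
reproducible pipeline. When fewer edges occur than there are retention
slots, all occurring edges are kept with a warning and the achieved
sparsity is reported honestly above the target.

Comparison groups: the high-HPA reference uses the guideline stratum; the
sedentary-time reference uses the empirical lowest tertile of mean daily ST
computed on the supplied cohort (the published 512 min/day cut is that
cohort's tertile, not a constant; the cut actually used is reported in the
results manifest). PA exposures are analysed against the high-HPA
reference, ST against the low-ST reference; the mapping is configurable.

Whether individual degrees entering regression were masked by the reference
network or computed on raw filtered networks is ambiguous in the source
description; both are implemented (`degree_mode = "masked"` by default,
with `"unmasked"` one switch away) and neither is asserted as the study's
choice. Masked degree can never exceed the individual's own degree or the
reference degree of the node, which the tests check.

## Association models (`assoc`)

Ordinary least squares with three nested covariate sets: model 1 — age,
sex, education level, MRI lag time, wake time (plus ICV for volume
outcomes); model 2 — additionally diabetes status; model 3 — additionally
BMI, systolic blood pressure, antihypertensive medication,
total-to-HDL-cholesterol ratio, lipid-modifying medication, smoking,
alcohol use, history of CVD. Analyses are complete-case per model (no
imputation is described for the source analysis); categorical covariates
are dummy-coded with the first level as reference, a choice the exposure
coefficient is invariant to.

"Standardized β" is read as **both** the continuous exposure and the
outcome z-scored on the analysis sample (the `stβ` convention), so the
coefficient is outcome SDs per exposure SD; because the table wording
("mean difference in node degree per SD") also admits an exposure-only
reading, `standardize = "exposure_only"` is provided and the two differ
exactly by the outcome SD. Confidence intervals use the t distribution on
residual degrees of freedom; associations are judged at p < 0.05 and
exposure × modifier interactions (sex, diabetes) at p ≤ 0.10, with the
modifier's main effect entering through the interaction block rather than
twice. No multiple-testing correction is applied across the exposure ×
outcome grid, as none is applied in the source analysis; results tables
say so.

## The synthetic cohort (`synth`)

The generator's defaults encode the study conditions; they are fixed, not
tuning knobs.

* **Covariates** follow the cohort's descriptive table: age ~ N(59.6,
  8.1²), 48.4% female, education 30.5/29.0/40.5%, BMI ~ N(26.6, 4.2²),
  diabetes prevalence 23.6% (log-odds increasing with age and BMI), and so
  on; ICV is ~1.45 l with a sex difference, and brain volumes are fixed
  fractions of ICV plus noise — conventional values, since the descriptive
  table does not report them.
* **Activity truth**: HPA is gamma-distributed (mean 24, SD ≈ 19 min/day —
  right-skewed and strictly positive, as cadence-thresholded stepping time
  must be), LPA normal (100 ± 33), ST normal (558 ± 99) truncated so that
  a positive standing-time remainder always exists, waking time 945 ± 50
  min/day. Exposures decline with age, BMI and diabetes, so confounder
  adjustment is non-trivial by construction.
* **Event logs** partition each day's wake window exactly into bouts whose
  class totals equal the day's truth minutes; LPA bout cadences are drawn
  in (60, 105) with floored step counts and HPA cadences in (115, 140)
  with ceilinged counts, so rounding can never move a bout across the 110
  steps/min boundary. The final wear day is short (device removal), and
  2% of middle days are shorter than 10 waking hours, so the validity
  rules are exercised on realistic inputs. Sedentary filler outside the
  wake window exercises window clipping.
* **Atlas**: regions are disjoint 2×2×2-voxel cuboids with a one-voxel
  background gap on a minimal 3-D grid — only label-lookup semantics
  matter downstream. Bilateral metadata assigns 8 basal-ganglia analogues
  (caudate, putamen, pallidum, thalamus × 2), 2 precentral analogues
  (primary motor cortex, excluded from the frontal aggregate), and cycles
  the remaining pairs over the four lobes and "other". Parcellations as
  small as 18 regions keep every group, which is what the fast test
  configurations use.
* **Networks**: per-edge population occurrence probabilities are Beta
  distributed with mean equal to the target density (0.25); each
  participant's edge-presence probabilities are these probabilities scaled
  to hit a per-participant target degree. The target is
  `μ + σ (β·z(HPA_inv) + Σγ·z(covariate) + g)` with σ = 0.8 degree units:
  the planted standardized effect β (default −0.08 per SD of inverted HPA)
  is exact in expectation because edge realization is unbiased around the
  target. The Bernoulli realization noise is counted toward the outcome's
  unit variance analytically and the Gaussian residual g makes up the
  remainder, so the *standardized* coefficient — which divides by the
  realized outcome SD — recovers β without bias; probability clipping at 1
  is the only approximation and is negligible at the default density.
  Present edges carry 3+Poisson streamline counts and log-normal tract
  volumes; 2% of absent edges carry spurious 1–2-streamline connections
  that the noise filter must remove.
* **Two connectome paths**: full streamline synthesis (polylines between
  region blocks, exercising assignment, tract volume and filtering
  geometrically) and direct matrix synthesis for fast statistical
  replicates. They realize the same presence/count structure; the
  geometric path is intended for small parcellations.

What the generator does **not** emulate: anatomical geometry, diffusion
signal or tractography biases, spatially correlated edge noise,
non-wear/misclassification error in the accelerometer, or missing data.
Passing recovery tests therefore demonstrate the pipeline's statistical
correctness under its own assumptions, not robustness to those real-data
complications.

## Simulation scale and numerical choices

Monte-Carlo recovery runs 200 replicates of n = 500 participants on a
20-region parcellation, and the interaction type-I simulation 500
replicates at n = 200 on 12 regions — sizes chosen so the whole suite runs
comfortably on one CPU while the Monte-Carlo standard error (~0.003) is far
below the planted effect. The recovery model is model 3, because the
ground-truth effect is conditional on the generator's confounders. The
sparsity acceptance run uses the full 120-region, 100-participant
configuration. Degenerate inputs error early and explicitly: zero-duration
bouts, non-positive ICV, zero-variance covariates, constant interaction
modifiers, parcellation mismatches, infeasible generator configurations
(odd region counts, too-small grids, densities implying less than one
expected edge).

## Known limitations

* The event generator aligns bouts to wake windows; straddling bouts are
  covered by hand-built fixtures in the tests rather than by the
  generator.
* The planted effect is defined on unmasked whole-brain degree;
  reference-masked degree shares the same linear signal but a different
  scale, so recovery simulations use the unmasked profile.
* Occurrence-probability clipping introduces a vanishing bias for very
  small parcellations combined with large planted effects.
* The empirical ST tertile uses `floor(n/3)` members with participant-id
  tie-breaking; other tertile conventions differ by at most one member.
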