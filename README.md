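# stepconn

Physical activity, sedentary time, and structural brain-network degree: a
tested R pipeline from accelerometer event logs and tractography
streamlines to confounder-adjusted standardized associations.

## The problem

Population imaging studies ask whether objectively measured physical
activity protects white-matter brain connectivity. Answering that requires
a long, brittle chain of processing:

1. **Accelerometer events → behaviour summaries.** Thigh-worn activPAL-style
   monitors emit posture *bouts* (sit/lie, stand, step) with step counts.
   Under the wear protocol, the first day and short final days are
   excluded, days need ≥ 10 waking hours to count, and stepping time is
   split at a cadence of 110 steps/min into low-intensity (LPA, ≤ 110) and
   high-intensity physical activity (HPA, > 110) within explicit waking
   windows. Daily means of sedentary time (ST), LPA, HPA and waking time
   are averaged over valid days; the 150 min/week guideline (≥ 21.4
   min/day of HPA) defines the high-HPA stratum.
2. **Streamlines → connectomes.** Each streamline connects the atlas
   regions holding its endpoints. The edge weight is the *tract volume* —
   distinct voxels visited by at least one streamline of the edge × voxel
   volume — normalized to intracranial volume; edges carried by only one
   or two streamlines are removed as noise.
3. **Group reference networks.** For a comparison group (guideline-meeting
   participants; the lowest sedentary-time tertile), edges are ranked by
   *occurrence* across members and proportionally thresholded to sparsity
   0.80: the 20% most common of the N(N−1)/2 possible edges are retained
   (1428 of 7140 for N = 120 regions), with a deterministic tie rule.
4. **Degree and models.** Node degree (binary count of incident edges,
   optionally masked by the reference network) is averaged whole-brain and
   over regional groups (four lobes, basal ganglia, primary motor cortex).
   Inverted activity exposures (low activity as risk) and ST are related
   to degree by OLS with three nested covariate models, reporting
   standardized β (outcome SDs per exposure SD) with 95% CI; interactions
   with sex and diabetes are judged at p ≤ 0.10.

Because cohort data of this kind are not openly deposited, `stepconn`
ships a **synthetic cohort generator** with known ground truth — event
logs, label atlases, streamline sets or connectome matrices, and
covariates drawn from the cohort's descriptive distributions, with a
planted standardized HPA→degree effect — so every stage is testable and
the full pipeline's statistical calibration is demonstrable.

## Worked example

```r
library(stepconn)

cfg <- synth_config(n_participants = 300, n_regions = 20, seed = 42)
res <- run_pipeline(pipeline_config(synth = cfg))

subset(res$associations, exposure == "hpa_inv" & outcome == "whole_brain")
#>  exposure     outcome model st_beta ci_low ci_high p_value n_used
#>   hpa_inv whole_brain     1  -0.134 -0.247 -0.0214  0.0199    300
#>   hpa_inv whole_brain     2  -0.128 -0.242 -0.0140  0.0278    300
#>   hpa_inv whole_brain     3  -0.130 -0.247 -0.0124  0.0303    300

round(res$percent_differences["basal_ganglia"], 1)
#> basal_ganglia
#>           4.9
round(res$manifest$st_tertile_cut_min_day, 1)
#> [1] 512.1
```

Reading this: one SD *less* HPA (the exposure is inverted) is associated
with ~0.13 SD lower whole-brain node degree, robust across the three
confounder models — the generator planted a negative effect, and the
pipeline recovers it with honest uncertainty. The basal-ganglia degree of
the below-guideline group is 4.9% lower than the guideline-meeting group's
(high-group mean as denominator), and the empirical lowest-ST tertile cut
for this cohort sits at 512 min/day. `write_results(res, "out/")` writes
all tables as TSV plus a JSON manifest with exclusion counts and achieved
sparsities.

Monte-Carlo calibration (the basis of the recovery tests):

```r
rec <- simulate_recovery(synth_config(n_participants = 500, n_regions = 20,
                                      make_events = FALSE, seed = 5000),
                         n_reps = 200)
c(mean = rec$mean_estimate, mcse = rec$mcse, coverage = rec$coverage)
```

The mean estimate lands within 2 Monte-Carlo SEs of the planted −0.08 and
95% CI coverage stays between 92% and 98%.

A thin command-line wrapper over `run_pipeline()` is installed at
`inst/scripts/pipeline.R` (`Rscript pipeline.R --config cfg.yaml --out out/`).

## Package layout

| path | contents |
|---|---|
| `R/accel.R` | bout validation, valid-day rules, cadence classification, summaries |
| `R/connectome.R` | streamline assignment, tract volumes, ICV normalization, noise filter, degree/sparsity |
| `R/refnet.R` | occurrence matrices, proportional thresholding, comparison groups, masked degrees |
| `R/assoc.R` | nested covariate models, standardized-β OLS, interaction tests |
| `R/synth.R` | synthetic atlases, streamlines, event logs, covariates, planted effects |
| `R/simulate.R` | Monte-Carlo recovery and interaction type-I utilities |
| `R/report.R` | pipeline orchestration, descriptive tables, percent differences, manifest |
| `R/io.R` | CSV/TSV/NIfTI/JSON/YAML readers and writers |
| `vignettes/stepconn-methods.Rmd` | the model, its assumptions, and every design decision |
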