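# datsbr

Simulation and reliability analysis of simplified dopamine-transporter
(DAT) quantification for [18F]FE-PE2I PET.

## What this is for

Striatal DAT availability separates Parkinson's disease (PD) patients from
controls and declines with progression. The reference-standard outcome is
the binding potential BP_ND estimated with the simplified reference tissue
model (SRTM) from a ~90-min dynamic scan; the clinical shortcut is a
specific binding ratio from a short static window,

    SBR = SUV_VOI / SUV_CER - 1,

computed either during the tracer's early peak equilibrium (15–45 min,
frames 24–29 of the standard 37-frame protocol; 18-min variant 27–45 min)
or during the late pseudo-equilibrium (51–81 min, frames 31–35; variant
57–75 min). Which window should be used, and what does the choice cost in
accuracy, test–retest reliability and longitudinal sensitivity? This
package gives quantitative answers on simulated cohorts with known ground
truth, for methodologists and physicists working on DAT-PET protocols:

* forward kinetic simulation of subject TACs (parametric plasma input,
  one-tissue reference region, SRTM target regions) on the 93-min,
  37-frame HRRT schedule, for cross-sectional (24 controls + 33 PD),
  test–retest (9 PD) and longitudinal (12 PD, −8 %/yr true decline)
  cohorts;
* a basis-function SRTM fitter (BP_ND, R1, k2; frame-duration-weighted
  least squares with local refinement) as the reference-standard
  quantification;
* SBR over the four named static windows with strict frame alignment and
  duration-weighted averaging;
* the full statistics set: bias, combined-sample COV and Cohen's d,
  pooled/Welch t with Bonferroni (2 VOIs), Mann–Whitney ROC AUC, absolute
  test–retest variability, one-way random ICC, SEM, annual percentage
  change, OLS agreement with BP_ND — plus exact reconstruction of the
  published effect sizes and COVs from group summary moments.

See `vignettes/dat-sbr-reliability.Rmd` for the models, conventions and
design decisions, and `analysis/01…05` for the narrative drivers that
write the result tables under `results/`.

## Worked example

```r
library(datsbr)
sched <- frame_schedule()
validate_schedule(sched)
#>        window start_min end_min first_frame last_frame
#> 1       early        15      45          24         29
#> 2 short_early        27      45          27         29
#> 3        late        51      81          31         35
#> 4  short_late        57      75          32         34

ref <- simulate_reference_tac(sched)                  # cerebellum
tgt <- srtm_forward(ref, kinetic_params(R1 = 0.9, k2 = 0.35, bp_nd = 3), sched)
fit_srtm(as.numeric(tgt), as.numeric(ref), sched)
#> <srtm_fit> R1 = 0.8956, k2 = 0.3522 /min, BP_ND = 2.9982, k2a = 0.0881 /min

ws <- sbr_windows(sched)
round(c(early = compute_sbr(tgt, ref, sched, ws$early)$sbr,
        late  = compute_sbr(tgt, ref, sched, ws$late)$sbr), 3)
#> early  late
#> 3.021 4.357
```

The fitter recovers the generating BP_ND = 3 to 0.06%. The early-window
SBR (3.02) sits on top of BP_ND while the late-window SBR (4.36)
overestimates it by ~45% — the reference region is still clearing during
the late window, which inflates the tissue ratio. The same asymmetry makes
late SBR more sensitive to between-scan clearance variability, and hence
less repeatable.

Group-level statistics reconstructed from the published cohort moments
(24 controls, 33 PD):

```r
tab <- moment_discrimination(published_group_moments())
subset(tab, outcome %in% c("bp_srtm", "sbr_early", "sbr_late"))
#>     outcome  region cohens_d cov_percent bias_controls  bias_pd
#> 1   bp_srtm caudate 1.434959    38.60740            NA       NA
#> 2   bp_srtm putamen 1.838430    64.37998            NA       NA
#> 3 sbr_early caudate 1.282050    36.04154     0.3355705  9.82659
#> 4 sbr_early putamen 1.756108    57.34424    -3.4883721 17.96875
#> 7  sbr_late caudate 1.231592    46.28155    66.7785235 64.16185
#> 8  sbr_late putamen 1.666954    75.56957    61.8604651 47.65625
```

Effect sizes are highest for SRTM BP_ND, slightly lower for early SBR and
lowest for late SBR; early SBR is nearly unbiased in controls while late
SBR overestimates BP_ND by ~50–65%.

A complete in-silico study (simulate → fit → quantify → report) is one
call: `run_study(study_config(seed = 1), out_dir = "results/study")`.

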