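---
title: "Simplified DAT quantification: models, windows and reliability metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplified DAT quantification: models, windows and reliability metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Striatal dopamine transporter (DAT) availability measured with
[18F]FE-PE2I PET separates Parkinson's disease (PD) patients from healthy
controls and declines with disease progression. The reference-standard
outcome, the non-displaceable binding potential BP~ND~ from the simplified
reference tissue model (SRTM), needs a ~90-min dynamic acquisition.
Clinical practice prefers a short static scan summarised as a specific
binding ratio,

$$\mathrm{SBR} = \frac{SUV_{VOI}}{SUV_{CER}} - 1,$$

the ratio of the mean striatal concentration to the mean cerebellar
concentration over a static window, minus one. Two window families are in
use: an *early peak equilibrium* window (15–45 min, with an 18-min variant
at 27–45 min) and a *late pseudo-equilibrium* window (51–81 min, variant
57–75 min). This package provides the machinery to study, on simulated
cohorts with known ground truth, how the window choice affects accuracy
(bias against BP~ND~), discriminative power (effect size, ROC AUC),
test–retest reliability (AbsVar, ICC, SEM) and longitudinal sensitivity
(annual percentage change), alongside exact recomputation of the
group-level statistics that follow from published cohort moments.

## Kinetic models

TACs are generated from a parametric plasma input
(tri-exponential with a linear ramp on the fastest phase; zero before the
arrival delay). The cerebellar reference region follows a one-tissue
compartment model,
$C_R(t) = K_{1}^{ref}\, e^{-k_2^{ref} t} \otimes C_p(t)$,
and each striatal target region follows the SRTM operational equation

$$C_T(t) = R_1 C_R(t) + \left(k_2 - R_1 k_{2a}\right)
  \left[C_R \otimes e^{-k_{2a} t}\right](t),
  \qquad k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

so the simulator and the fitter share no code path but agree on the model
family. The identity $k_{2a} = k_2/(1+BP_{ND})$ is maintained exactly on
both sides.

Estimation uses the standard basis-function solver: for each candidate
$k_{2a}$ on a log-spaced grid (128 points, 0.006–0.6 min⁻¹ — generously
bracketing the $k_{2a}$ implied by $k_2 \in [0.2, 0.6]$ min⁻¹ and
$BP_{ND} \in [0, 6]$) the model is linear in $(R_1,\, k_2 - R_1 k_{2a})$
and solved by frame-duration-weighted least squares; the grid minimiser is
then refined by bounded one-dimensional optimisation on $\log k_{2a}$
between its neighbouring grid points. Duration weights approximate count
statistics without requiring a calibrated noise model. A fit whose optimum
sits on the grid boundary is flagged and not marked converged.

### Numerical choices

* Convolutions run on a 1-s uniform grid (frame durations span 10–360 s, so
  frame-resolution convolution would be badly inaccurate for the early
  frames). The exponential kernels are integrated with a second-order
  exponential integrator that is exact for piecewise-linear inputs, so the
  1-s grid leaves discretisation errors near 0.01% — the test suite checks
  the forward curves against an independent ODE solution to 0.1%.
* Frame values are trapezoidal averages of the instantaneous curve over
  each frame; window means are duration-weighted
  ($\sum v_i \Delta t_i / \sum \Delta t_i$), since plain averaging of
  unequal 180-s and 360-s frames would bias the early window. Whether the
  original pipelines weighted by duration is not documented anywhere we
  know of; this is our interpretation and it is stated as such.
* Window edges must coincide with frame boundaries. Partial-frame
  interpolation would silently change SBR values, so misalignment is a
  loud error that names the nearest frame edges.
* When a fitted TAC arrives as frame values only, the reference curve is
  rebuilt by linear interpolation at frame midpoints (zero at injection).
  The noise-free round trip simulate → fit recovers BP~ND~ to well under
  1% despite this approximation.

## The synthetic cohorts

The generator emulates the three arms of the reference HRRT study on its
37-frame, 93-min schedule (8×10 s, 5×20 s, 4×30 s, 4×60 s, 4×180 s,
12×360 s):

* **Cross-sectional**: 24 controls and 33 PD patients, with per-region
  BP~ND~ drawn from truncated normals matching the published group moments
  (controls caudate 2.98 ± 0.66, putamen 4.30 ± 0.79; PD 1.73 ± 0.58 and
  1.28 ± 0.56). Truncation at 0.05 keeps binding positive while matching
  mean ± SD reporting directly; BP~ND~, R1 and k2 are drawn independently
  because only marginal moments are published.
* **Test–retest**: 9 PD patients scanned twice days apart
  (interval ≈ 12/365 yr, no true change).
* **Longitudinal**: 12 PD patients scanned 2 years apart with a true
  decline of −8 %/yr applied compound,
  $BP^{(2)} = BP^{(1)} (1 - 0.08)^2$.

R1 and k2 default to 0.90 ± 0.06 and 0.35 ± 0.06 min⁻¹ — mid-range values
for reversible striatal tracers. Reference kinetics default to
$K_1^{ref} = 0.15$ mL·cm⁻³·min⁻¹ and $k_2^{ref} = 0.05$ min⁻¹ with a 10%
between-subject CV. The input-function defaults were set, once, so that
the cerebellar TAC peaks within the first quarter of the scan and clears
severalfold by the end — the shape that produces an early transient peak
equilibrium (window ratio crossing BP~ND~) followed by a late
pseudo-equilibrium whose ratio sits well above BP~ND~. They are
configuration values, not claims about FE-PE2I plasma kinetics.

Two within-subject perturbations model repeat-scan variability:

* **Frame noise**: Gaussian with variance
  $\alpha^2\, C_i\, \bar{C}_{scan} / \Delta t_i$ ($\Delta t$ in minutes), a
  standard count-statistics heuristic made unit-free by the scan-mean
  factor; $\alpha = 0.05$ puts test–retest AbsVar of the 30-min windows in
  the single-digit percent range typical of this tracer. TAC-level
  simulation cannot identify the true noise/jitter split from published
  group tables, so these are calibrated defaults, stated once.
* **Session jitter**: multiplicative Gaussian perturbation (SD 3%) of the
  realised kinetic parameters per scan, modelling physiological and
  repositioning variability. The clearance component scales the plasma
  washout phases and the reference efflux rate *together* — clearance is a
  subject-level property of the tracer, and jittering $k_2^{ref}$ alone
  would be absorbed by the slower plasma tail. A `jitter_scope` switch
  restricts the jitter to clearance only, which is the clean experiment
  for the question "how sensitive is each window to clearance
  variability?" (answer: SRTM BP~ND~ is essentially immune, late SBR is
  hit hardest; see `analysis/04_window_mechanism.R`).

Randomness is split deterministically from one master seed per subject
(parameter draws) and per subject–session with separate jitter and noise
streams, so any subject can be regenerated alone and two configurations
differing only in jitter share their noise draws (common random numbers).

What the generator does **not** emulate: image-space effects (PSF,
reconstruction, motion), attenuation/scatter, demographic covariates,
inter-region parameter correlation, and arterial input variability beyond
the clearance factor. An optional TAC-level partial-volume mixing switch
(`apply_partial_volume_mixing`) crudely imitates resolution loss — it
reproduces the qualitative SBR decrease seen when images are smoothed to
clinical resolution, nothing more. Passing tests on these cohorts
therefore show that the *estimators and their comparative behaviour* are
implemented correctly, not that real-scanner values (AUC ≈ 0.99,
ICC ≈ 0.95, AbsVar ≈ 7%) would be reproduced from raw images.

## Statistics

All formulas operate on the outcome tables produced by
`quantify_cohort()` and are also exposed directly:

* bias $= 100(\overline{SBR} - \overline{BP})/\overline{BP}$;
  COV $= 100\,\sigma/\mu$ (sample SD, $n-1$), over the combined
  controls + patients sample;
* Cohen's d $= (\mu_c - \mu_{PD})/\sigma_{combined}$ where the
  standardiser is the **combined two-group sample SD**, not the classical
  within-group pooled SD. This convention is forced by internal
  consistency: reconstructed from the published group moments it
  reproduces the printed effect sizes (1.44/1.84 for BP~ND~, 1.23/1.67 for
  late SBR) and the printed combined COVs, whereas the within-group pooled
  form gives ≈ 2.0 for caudate BP~ND~. `cohens_d_moments()` implements the
  exact moment reconstruction and is tested to be algebraically identical
  to the raw-sample computation.
* two-sample t: pooled-variance Student's t by default (the source of the
  convention says only "two-sample t test"); Welch by flag. Bonferroni for
  the two striatal VOIs by p-multiplication capped at 1.
* ROC AUC in the Mann–Whitney form with half-credit ties, oriented for
  controls-higher discrimination;
* AbsVar $= 100|v_2 - v_1| / \bar v$; ICC(1) from the one-way random
  ANOVA decomposition; SEM $= \sigma\sqrt{1-\mathrm{ICC}}$ with $\sigma$
  over all pooled measurements; APC
  $= 100 (v_2 - v_1)/v_1 / \Delta t_{yr}$ per subject, summarised as
  mean ± SD. Note the APC definition is baseline-relative, so a true
  compound decline of −8 %/yr over 2 years is *correctly* estimated as
  $100((0.92)^2-1)/2 = -7.68$ %/yr; the tests pin this closed form.
* linear agreement between SBR and BP~ND~ by OLS with $r^2$ the squared
  Pearson correlation.

Degenerate inputs (zero reference mean, zero combined SD, identical
measurements for ICC, non-positive baselines) raise errors rather than
returning NaN; all SDs use denominator $n-1$.

## Problem sizes and determinism

The default study (`run_study(study_config())`) quantifies
57 + 18 + 24 = 99 scans — a few seconds of compute — and is bit-for-bit
reproducible from its master seed. The test suite runs the solver
identity over a 3×3×3 parameter grid, 200-replicate noise recovery, and
1000 randomised oracle-equivalence instances for AUC/ICC; these sizes were
chosen to estimate each property comfortably while keeping the whole
suite around half a minute.

## Known limitations

* TAC-level only: no image I/O, no voxelwise parametric maps, no Logan
  graphical analysis.
* The published cohort's subject-level data are not available, so
  real-data AUC/ICC/SEM/APC values cannot be recomputed — only the
  moment-derived statistics and the directional mechanisms are
  reproducible, and the package is explicit about which is which.
* The basis-function solver assumes the reference TAC is noise-suppressed
  enough to serve as a regressor (as SRTM itself does); very high noise
  levels bias $k_{2a}$ towards the grid interior.
* `session_spec` applies jitter independently per scan; slow physiological
  drift between sessions is not modelled.
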