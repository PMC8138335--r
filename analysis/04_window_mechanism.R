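#!/usr/bin/env Rscript
# Why the late pseudo-equilibrium window is the less reliable one.
# (a) Noise-free window bias as a function of true BP_ND: the late-window
#     ratio sits far above BP_ND because the reference region keeps
#     clearing, while the early window straddles the transient peak
#     equilibrium where the ratio crosses BP_ND.
# (b) Clearance sensitivity: jittering only the tracer clearance (plasma
#     washout + cerebellar efflux) between two otherwise identical scans
#     inflates late-SBR test-retest variability more than early-SBR.

library(datsbr)

dir.create("results", showWarnings = FALSE)
sched <- frame_schedule()
ws <- sbr_windows(sched)
ref <- simulate_reference_tac(sched)

## (a) bias-vs-BP curves, noise-free ---------------------------------------
bias_tab <- do.call(rbind, lapply(seq(0.5, 5, by = 0.5), function(bp) {
  tgt <- srtm_forward(ref, kinetic_params(0.9, 0.35, bp), sched)
  data.frame(
    true_bp = bp,
    bias_early = bias_percent(compute_sbr(tgt, ref, sched, ws$early)$sbr, bp),
    bias_late = bias_percent(compute_sbr(tgt, ref, sched, ws$late)$sbr, bp)
  )
}))
cat("-- Noise-free window bias vs true BP_ND --\n")
print(bias_tab, digits = 2, row.names = FALSE)
write.csv(bias_tab, "results/window_bias_vs_bp.csv", row.names = FALSE)

## (b) clearance-jitter experiment -----------------------------------------
pd <- default_groups()$pd
arm <- list(pd = group_spec("pd", 9, bp = pd$bp))
jittered <- quantify_cohort(simulate_cohort(
  arm, session_spec(2, 12 / 365, 0.03, 0, jitter_scope = "reference_clearance"),
  noise_model(0), seed = 732))
rj <- report_retest(jittered)
cat("\n-- AbsVar induced by 3% session-to-session clearance jitter --\n")
print(rj[, c("outcome", "region", "absvar_mean", "absvar_sd")],
      digits = 3, row.names = FALSE)
write.csv(rj, "results/clearance_jitter_absvar.csv", row.names = FALSE)

cat("\nReadout: late-window SBR bias exceeds early-window bias at every",
    "BP_ND level, and pure clearance jitter produces clearly larger",
    "late-window AbsVar in both regions - the mechanism behind the",
    "recommendation to prefer the early peak-equilibrium window for",
    "quantitative use.\n")
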