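small_groups <- function(nc = 3, np = 3) {
  list(
    controls = group_spec("controls", nc,
                          bp = list(caudate = c(2.98, 0.66), putamen = c(4.30, 0.79))),
    pd = group_spec("pd", np,
                    bp = list(caudate = c(1.73, 0.58), putamen = c(1.28, 0.56)))
  )
}

test_that("parameter draws are deterministic and respect degenerate SDs", {
  g <- group_spec("controls", 5, bp = list(caudate = c(2.98, 0)),
                  r1 = c(0.9, 0), k2 = c(0.35, 0))
  p <- sample_subject_params(g, "caudate", n = 4, seed = 7)
  expect_equal(p$bp_nd, rep(2.98, 4))
  expect_equal(p$R1, rep(0.9, 4))
  g2 <- default_groups()$controls
  a <- sample_subject_params(g2, "caudate", n = 50, seed = 11)
  b <- sample_subject_params(g2, "caudate", n = 50, seed = 11)
  expect_identical(a, b)
})

test_that("draws reproduce the target moments at large n", {
  g <- default_groups()$controls
  p <- sample_subject_params(g, "caudate", n = 10000, seed = 99)
  expect_lt(abs(mean(p$bp_nd) - 2.98) / 2.98, 0.02)
  expect_lt(abs(sd(p$bp_nd) - 0.66) / 0.66, 0.05)
  expect_true(all(p$bp_nd >= 0.05))
})

test_that("impossible truncation is a spec error", {
  g <- group_spec("pd", 3, bp = list(caudate = c(-5, 0.1)))
  expect_error(sample_subject_params(g, "caudate", n = 2, seed = 1),
               "truncation")
})

test_that("cohort simulation is fully deterministic under the master seed", {
  a <- simulate_cohort(small_groups(), session_spec(2, 12 / 365, 0.03, 0),
                       noise_model(0.05), seed = 5)
  b <- simulate_cohort(small_groups(), session_spec(2, 12 / 365, 0.03, 0),
                       noise_model(0.05), seed = 5)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$tacs, b$tacs)
  c2 <- simulate_cohort(small_groups(), session_spec(2, 12 / 365, 0.03, 0),
                        noise_model(0.05), seed = 6)
  expect_false(identical(a$tacs, c2$tacs))
})

test_that("no change, no jitter and no noise gives identical sessions", {
  sim <- simulate_cohort(small_groups(2, 2), session_spec(2, 0, 0, 0),
                         noise_model(0), seed = 3)
  for (sid in unique(sim$manifest$subject_id)) {
    expect_identical(as.numeric(sim$tacs[[paste0(sid, "_s1")]]$putamen),
                     as.numeric(sim$tacs[[paste0(sid, "_s2")]]$putamen))
  }
})

test_that("true BP declines by the compound APC factor across sessions", {
  sim <- simulate_cohort(small_groups(2, 2), session_spec(2, 2, 0, -8),
                         noise_model(0), seed = 3)
  m <- sim$manifest
  s1 <- m[m$session == 1, ]
  s2 <- m[m$session == 2, ]
  expect_equal(s2$true_bp_putamen, 0.8464 * s1$true_bp_putamen, tolerance = 1e-12)
  expect_equal(s2$true_bp_caudate, (1 - 0.08)^2 * s1$true_bp_caudate,
               tolerance = 1e-12)
})

test_that("noise-free pipeline recovers every subject's BP within 1%", {
  sim <- simulate_cohort(small_groups(3, 3), session_spec(1, 0, 0, 0),
                         noise_model(0), seed = 17)
  oc <- quantify_cohort(sim)
  bp <- oc[oc$outcome == "bp_srtm", ]
  expect_true(all(abs(bp$value - bp$true_bp) / bp$true_bp < 0.01))
})

test_that("group-level COV of true BP approaches the generating SD/mean", {
  g <- list(controls = group_spec("controls", 400,
                                  bp = list(caudate = c(2.98, 0.66))))
  sim <- simulate_cohort(g, session_spec(1, 0, 0, 0), noise_model(0), seed = 8)
  cov_true <- cov_percent(sim$manifest$true_bp_caudate)
  expect_lt(abs(cov_true - 100 * 0.66 / 2.98), 2.5)
})

test_that("partial-volume mixing has identity and fixed-point behaviour", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  tgt <- srtm_forward(ref, kinetic_params(0.9, 0.35, 4.3), sched)
  tacs <- list(putamen = as.numeric(tgt), cerebellum = as.numeric(ref))
  expect_identical(apply_partial_volume_mixing(tacs, 0), tacs)
  same <- list(putamen = as.numeric(ref), cerebellum = as.numeric(ref))
  mixed_same <- apply_partial_volume_mixing(same, 0.2)
  expect_equal(mixed_same$putamen, same$putamen)
  expect_equal(mixed_same$cerebellum, same$cerebellum)
  expect_error(apply_partial_volume_mixing(tacs, 0.5), "m must")
  expect_error(apply_partial_volume_mixing(tacs, -0.1), "m must")
})

test_that("partial-volume mixing lowers SBR on a control-like subject", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  tgt <- srtm_forward(ref, kinetic_params(0.9, 0.35, 4.3), sched)
  tacs <- list(putamen = as.numeric(tgt), cerebellum = as.numeric(ref))
  mixed <- apply_partial_volume_mixing(tacs, 0.2)
  w <- sbr_windows(sched)$early
  expect_lt(compute_sbr(mixed$putamen, mixed$cerebellum, sched, w)$sbr,
            compute_sbr(tacs$putamen, tacs$cerebellum, sched, w)$sbr)
})

test_that("frame noise scales with alpha and vanishes at alpha = 0", {
  sched <- default_sched
  ref <- as.numeric(simulate_reference_tac(sched))
  expect_identical(datsbr:::add_frame_noise(ref, sched, 0), ref)
  set.seed(2)
  noisy <- datsbr:::add_frame_noise(ref, sched, 0.05)
  expect_false(identical(noisy, ref))
  # long late frames get absolutely smaller noise than short early frames
  set.seed(2)
  reps <- replicate(200, datsbr:::add_frame_noise(ref, sched, 0.05))
  sds <- apply(reps - ref, 1, sd)
  expect_gt(mean(sds[9:13]), mean(sds[30:37]))
})
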