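test_that("kinetic_params maintains the k2a identity and rejects bad values", {
  kp <- kinetic_params(0.9, 0.35, 4)
  expect_equal(kp$k2a, 0.35 / 5)
  expect_error(kinetic_params(0, 0.35, 4), "R1")
  expect_error(kinetic_params(0.9, -0.1, 4), "k2")
  expect_error(kinetic_params(0.9, 0.35, -0.5), "bp_nd")
})

test_that("reference TAC matches the ODE oracle within 0.1%", {
  skip_if_not_installed("deSolve")
  sched <- default_sched
  inp <- input_function()
  got <- simulate_reference_tac(sched, 0.15, 0.05, inp)
  want <- ode_reference_oracle(sched, 0.15, 0.05, inp)
  expect_lt(max(abs(got - want)) / max(want), 1e-3)
})

test_that("reference TAC is linear in K1ref and zero for null input", {
  sched <- default_sched
  r1 <- simulate_reference_tac(sched, 0.15, 0.05)
  r2 <- simulate_reference_tac(sched, 0.30, 0.05)
  expect_equal(as.numeric(r2), 2 * as.numeric(r1))
  expect_true(all(as.numeric(r1) >= 0))
  r0 <- simulate_reference_tac(sched, 0, 0.05)
  expect_equal(as.numeric(r0), rep(0, 37))
  expect_error(simulate_reference_tac(frame_schedule(list(c(1, 0))), 0.15, 0.05))
})

test_that("forward SRTM matches the joint-ODE oracle within 0.1%", {
  skip_if_not_installed("deSolve")
  sched <- default_sched
  inp <- input_function()
  ref <- simulate_reference_tac(sched, 0.15, 0.05, inp)
  got <- srtm_forward(ref, kinetic_params(0.9, 0.35, 4), sched)
  want <- ode_srtm_oracle(sched, 0.15, 0.05, inp, 0.9, 0.35, 4)$target
  expect_lt(max(abs(got - want)) / max(want), 1e-3)
})

test_that("forward SRTM degenerates to the reference when R1 = 1, BP = 0", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  out <- srtm_forward(ref, kinetic_params(1, 0.35, 0), sched)
  expect_equal(as.numeric(out), as.numeric(ref))
  zero <- ref; zero[] <- 0; attr(zero, "fine")[] <- 0
  expect_equal(as.numeric(srtm_forward(zero, kinetic_params(0.9, 0.35, 4), sched)),
               rep(0, 37))
})

test_that("frame-averaged forward model converges as frames shrink", {
  # slicing the scan into ever-shorter frames drives the frame averages to
  # the instantaneous curve at the frame midpoints (second-order in the
  # frame duration, limited by curvature at the bolus peak)
  inp <- input_function()
  err_at <- function(dur_s) {
    sched <- frame_schedule(list(c(5580 / dur_s, dur_s)))
    ref <- simulate_reference_tac(sched, input = inp)
    inst <- attr(ref, "fine")
    grid <- datsbr:::fine_grid(sched, 1)
    at_mid <- approx(grid$t_min, inst, xout = frame_mid_min(sched))$y
    max(abs(ref - at_mid)) / max(inst)
  }
  errs <- vapply(c(60, 10, 2), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
  # roughly second-order: 5x shorter frames cut the error by well over 5x
  expect_lt(errs[3], errs[2] / 5)
})

test_that("fit recovers forward parameters exactly enough, noise-free", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  tgt <- srtm_forward(ref, kinetic_params(0.9, 0.35, 4), sched)
  # measured path: frame values only, fine curves dropped
  fit <- fit_srtm(as.numeric(tgt), as.numeric(ref), sched)
  expect_lt(abs(fit$bp_nd - 4) / 4, 0.01)
  expect_lt(abs(fit$R1 - 0.9), 0.02)
  expect_true(fit$converged)
  expect_equal(fit$k2a, fit$k2 / (1 + fit$bp_nd), tolerance = 1e-10)
})

test_that("forward-then-fit is the identity across the parameter grid", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  basis <- srtm_basis(as.numeric(ref), sched)
  for (R1 in c(0.7, 0.9, 1.1)) {
    for (k2 in c(0.2, 0.35, 0.6)) {
      for (bp in c(0.5, 2, 6)) {
        tgt <- srtm_forward(ref, kinetic_params(R1, k2, bp), sched)
        fit <- fit_srtm(as.numeric(tgt), basis)
        expect_lt(abs(fit$bp_nd - bp) / bp, 0.01)
      }
    }
  }
})

test_that("identity target yields BP ~ 0 and R1 ~ 1", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  fit <- fit_srtm(as.numeric(ref), as.numeric(ref), sched)
  expect_lt(abs(fit$bp_nd), 0.02)
  expect_equal(fit$R1, 1, tolerance = 0.01)
})

test_that("fit is invariant to common rescaling of both TACs", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  tgt <- srtm_forward(ref, kinetic_params(0.85, 0.3, 2.5), sched)
  f1 <- fit_srtm(as.numeric(tgt), as.numeric(ref), sched)
  f2 <- fit_srtm(1e3 * as.numeric(tgt), 1e3 * as.numeric(ref), sched)
  expect_equal(f1$bp_nd, f2$bp_nd, tolerance = 1e-8)
  expect_equal(f1$R1, f2$R1, tolerance = 1e-8)
})

test_that("degenerate TACs are rejected", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  expect_error(fit_srtm(rep(0, 37), as.numeric(ref), sched), "degenerate")
  expect_error(fit_srtm(as.numeric(ref), rep(0, 37), sched), "degenerate")
})

test_that("median recovered BP over noisy replicates stays within 5%", {
  sched <- default_sched
  ref <- simulate_reference_tac(sched)
  tgt <- srtm_forward(ref, kinetic_params(0.9, 0.35, 3), sched)
  basis <- srtm_basis(as.numeric(ref), sched)
  set.seed(1234)
  bps <- replicate(200, {
    noisy <- datsbr:::add_frame_noise(as.numeric(tgt), sched, 0.05)
    fit_srtm(noisy, basis)$bp_nd
  })
  expect_lt(abs(median(bps) - 3) / 3, 0.05)
})
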