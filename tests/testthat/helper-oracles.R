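# Independent oracles used across the suite. They share no code with the
# package internals: kinetic curves are solved as ODE systems (deSolve,
# dense output, trapezoid frame averaging), AUC is brute-force pair
# counting, ICC comes from explicit one-way ANOVA sums of squares.

default_sched <- frame_schedule()

# One-tissue reference curve by ODE integration, frame-averaged on a dense
# trapezoid grid (dt_oracle seconds).
ode_reference_oracle <- function(schedule, K1ref, k2ref, input, dt_oracle = 0.1) {
  times <- seq(0, max(schedule$end_s), by = dt_oracle) / 60
  sol <- deSolve::ode(
    y = c(CR = 0), times = times,
    func = function(t, y, parms) {
      list(K1ref * input_function_value(t, input) - k2ref * y[1])
    },
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  trapz_frame_avg(sol[, "CR"], times * 60, schedule)
}

# SRTM target curve by joint ODE integration:
#   dCR/dt = K1ref*Cp - k2ref*CR
#   dCT/dt = R1*dCR/dt + k2*CR - k2a*CT
ode_srtm_oracle <- function(schedule, K1ref, k2ref, input, R1, k2, bp_nd,
                            dt_oracle = 0.1) {
  k2a <- k2 / (1 + bp_nd)
  times <- seq(0, max(schedule$end_s), by = dt_oracle) / 60
  sol <- deSolve::ode(
    y = c(CR = 0, CT = 0), times = times,
    func = function(t, y, parms) {
      dCR <- K1ref * input_function_value(t, input) - k2ref * y[1]
      dCT <- R1 * dCR + k2 * y[1] - k2a * y[2]
      list(c(dCR, dCT))
    },
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  list(ref = trapz_frame_avg(sol[, "CR"], times * 60, schedule),
       target = trapz_frame_avg(sol[, "CT"], times * 60, schedule))
}

trapz_frame_avg <- function(curve, t_s, schedule) {
  vapply(seq_len(nrow(schedule)), function(k) {
    sel <- t_s >= schedule$start_s[k] - 1e-9 & t_s <= schedule$end_s[k] + 1e-9
    tt <- t_s[sel]; vv <- curve[sel]
    sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2) / (max(tt) - min(tt))
  }, numeric(1))
}

# Probability that a random control value exceeds a random patient value,
# counting every pair explicitly (ties get half credit).
brute_force_auc <- function(controls, patients) {
  cnt <- 0
  for (x in controls) for (y in patients) {
    cnt <- cnt + (x > y) + 0.5 * (x == y)
  }
  cnt / (length(controls) * length(patients))
}

# ICC(1) from explicit one-way ANOVA sums of squares over an n x k matrix.
anova_icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssb <- k * sum((rowMeans(m) - grand)^2)
  ssw <- sum((m - rowMeans(m))^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}
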