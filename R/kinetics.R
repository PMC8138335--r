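#' Target-region kinetic parameters
#'
#' SRTM parameterisation of a target region relative to a reference region:
#' `R1` is the target-to-reference delivery ratio, `k2` (1/min) the target
#' efflux rate and `BP_ND` the non-displaceable binding potential. The
#' apparent efflux rate `k2a = k2 / (1 + BP_ND)` is derived, never stored
#' independently.
#'
#' @param R1 delivery ratio, > 0.
#' @param k2 efflux rate (1/min), > 0.
#' @param bp_nd binding potential, >= 0.
#' @return a `kinetic_params` list with fields `R1`, `k2`, `bp_nd`, `k2a`.
#' @export
kinetic_params <- function(R1, k2, bp_nd) {
  if (!is.finite(R1) || R1 <= 0) stop("R1 must be a positive finite number")
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be a positive finite number")
  if (!is.finite(bp_nd) || bp_nd < 0) stop("bp_nd must be finite and >= 0")
  structure(list(R1 = R1, k2 = k2, bp_nd = bp_nd, k2a = k2 / (1 + bp_nd)),
            class = "kinetic_params")
}

# Fine uniform time grid (node samples t = 0, dt, ..., T) covering the
# scan, in minutes. dt_s = 1 s resolves the 10 s early frames; frame
# boundaries in the default protocol fall exactly on grid nodes.
fine_grid <- function(schedule, dt_s = 1) {
  total_s <- max(schedule$end_s)
  nstep <- round(total_s / dt_s)
  list(t_min = (0:nstep) * dt_s / 60, dt_min = dt_s / 60, dt_s = dt_s,
       n = nstep + 1L, nstep = nstep)
}

# Convolution of a sampled curve with an exponential kernel exp(-k*t),
# exact for piecewise-linear f (second-order exponential integrator,
# O(n) via a recursive filter): y_i = E*y_{i-1} + dt*(I1*f_{i-1} + I2*f_i)
# with E = exp(-k*dt) and I1, I2 the linear-interpolation weights.
conv_exp <- function(f, k, dt_min) {
  n <- length(f)
  if (k <= 0) stop("exponential kernel rate must be positive")
  th <- k * dt_min
  E <- exp(-th)
  I1 <- (1 - (1 + th) * E) / th^2
  I2 <- (th - 1 + E) / th^2
  x <- dt_min * (I1 * f[-n] + I2 * f[-1])
  y <- stats::filter(x, E, method = "recursive")
  c(0, as.numeric(y))
}

# Average a fine-grid curve over schedule frames by trapezoidal quadrature
# (frame boundaries coincide with grid nodes).
frame_average <- function(curve, schedule, grid) {
  i0 <- round(schedule$start_s / grid$dt_s)
  i1 <- round(schedule$end_s / grid$dt_s)
  if (any(i1 > grid$nstep) || any(i1 <= i0)) stop("schedule does not fit the fine grid")
  cs <- cumsum(curve)
  vapply(seq_len(nrow(schedule)), function(k) {
    a <- i0[k] + 1L; b <- i1[k] + 1L
    s <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    (s - 0.5 * (curve[a] + curve[b])) / (b - a)
  }, numeric(1))
}

with_fine <- function(values, fine, grid) {
  attr(values, "fine") <- fine
  attr(values, "grid_dt_s") <- grid$dt_s
  values
}

# Recover a fine-grid curve for a frame-level TAC: use the simulation-time
# instantaneous curve when it is attached, otherwise interpolate the frame
# values linearly at frame midpoints (0 at injection, flat after the last
# midpoint).
fine_curve <- function(values, schedule, grid) {
  fine <- attr(values, "fine")
  if (!is.null(fine) && length(fine) == grid$n &&
      isTRUE(all.equal(attr(values, "grid_dt_s"), grid$dt_s))) {
    return(fine)
  }
  mids <- frame_mid_min(schedule)
  stats::approx(x = c(0, mids), y = c(0, as.numeric(values)),
                xout = grid$t_min, rule = 2)$y
}

#' Simulate a reference-region TAC
#'
#' One-tissue compartment model for the reference region (cerebellum):
#' `C_R(t) = K1ref * exp(-k2ref * t) (x) C_p(t)`, convolved on a fine
#' uniform grid and averaged over each acquisition frame.
#'
#' @param schedule a [frame_schedule()] object.
#' @param K1ref delivery rate constant (mL/cm^3/min), > 0.
#' @param k2ref reference efflux rate (1/min), > 0.
#' @param input an [input_function()] parameter set.
#' @param dt_s fine-grid step (s).
#' @return numeric vector of frame-averaged concentrations (one per frame)
#'   with the instantaneous fine-grid curve attached as attribute `"fine"`.
#' @export
simulate_reference_tac <- function(schedule, K1ref = 0.15, k2ref = 0.05,
                                   input = input_function(), dt_s = 1) {
  assert_schedule(schedule)
  if (!is.finite(K1ref) || K1ref < 0 || !is.finite(k2ref) || k2ref <= 0) {
    stop("K1ref must be >= 0 and k2ref > 0")
  }
  grid <- fine_grid(schedule, dt_s)
  cp <- input_function_value(grid$t_min, input)
  cr <- K1ref * conv_exp(cp, k2ref, grid$dt_min)
  cr[cr < 0] <- 0
  with_fine(frame_average(cr, schedule, grid), cr, grid)
}

#' Forward SRTM model: target TAC from a reference TAC
#'
#' Operational equation of the simplified reference tissue model:
#' `C_T(t) = R1 * C_R(t) + (k2 - R1 * k2a) * [C_R (x) exp(-k2a t)](t)`
#' with `k2a = k2 / (1 + BP_ND)`, evaluated on a fine grid and averaged
#' over the acquisition frames.
#'
#' @param ref frame-level reference TAC (from [simulate_reference_tac()] or
#'   measured); a fine-grid curve attached as attribute `"fine"` is used
#'   when present, otherwise the frame values are interpolated.
#' @param params a [kinetic_params()] object.
#' @param schedule a [frame_schedule()] object.
#' @param dt_s fine-grid step (s).
#' @return frame-averaged target TAC with the fine-grid curve attached.
#' @export
srtm_forward <- function(ref, params, schedule, dt_s = 1) {
  assert_schedule(schedule)
  if (!inherits(params, "kinetic_params")) stop("`params` must be kinetic_params")
  grid <- fine_grid(schedule, dt_s)
  cr <- fine_curve(ref, schedule, grid)
  coef2 <- params$k2 - params$R1 * params$k2a
  ct <- params$R1 * cr +
    coef2 * conv_exp(cr, params$k2a, grid$dt_min)
  with_fine(frame_average(ct, schedule, grid), ct, grid)
}

#' Precompute SRTM basis functions for a reference TAC
#'
#' The basis-function SRTM solver regresses the target TAC on the reference
#' TAC and on `B_j = C_R (x) exp(-k2a_j t)` over a grid of candidate `k2a`
#' values. The basis depends only on the reference curve and can be shared
#' across all target regions of one scan.
#'
#' @param ref frame-level reference TAC.
#' @param schedule a [frame_schedule()] object.
#' @param k2a_grid candidate apparent efflux rates (1/min); default 128
#'   log-spaced points on 0.006-0.6.
#' @param dt_s fine-grid step (s).
#' @return an `srtm_basis` object used by [fit_srtm()].
#' @export
srtm_basis <- function(ref, schedule,
                       k2a_grid = exp(seq(log(0.006), log(0.6), length.out = 128)),
                       dt_s = 1) {
  assert_schedule(schedule)
  grid <- fine_grid(schedule, dt_s)
  cr <- fine_curve(ref, schedule, grid)
  B <- vapply(k2a_grid, function(k2a) {
    frame_average(conv_exp(cr, k2a, grid$dt_min), schedule, grid)
  }, numeric(nrow(schedule)))
  structure(list(ref_frames = as.numeric(ref), cr_fine = cr, grid = grid,
                 k2a_grid = k2a_grid, B = B, schedule = schedule),
            class = "srtm_basis")
}

# Weighted least squares of y on (x1, x2) through the normal equations;
# returns coefficients and weighted RSS.
wls2 <- function(y, x1, x2, w) {
  X <- cbind(x1, x2)
  XtW <- t(X * w)
  A <- XtW %*% X
  b <- XtW %*% y
  theta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(theta)) return(list(theta = c(NA, NA), wrss = Inf))
  r <- y - X %*% theta
  list(theta = as.numeric(theta), wrss = sum(w * r^2))
}

#' Fit the simplified reference tissue model to a TAC pair
#'
#' Basis-function search over the apparent efflux rate `k2a`: for each
#' candidate the model is linear in `(R1, k2 - R1*k2a)` and solved by
#' frame-duration-weighted least squares; the grid minimiser is then
#' refined by bounded one-dimensional optimisation between its neighbouring
#' grid points. `BP_ND = k2 / k2a - 1`.
#'
#' @param target frame-level target TAC (caudate or putamen).
#' @param ref frame-level reference TAC (cerebellum), or an [srtm_basis()]
#'   precomputed from it.
#' @param schedule a [frame_schedule()] object (ignored when `ref` is a basis).
#' @param k2a_grid candidate `k2a` grid (ignored when `ref` is a basis).
#' @param dt_s fine-grid step (s).
#' @param refine logical; perform local refinement around the grid minimum.
#' @return an `srtm_fit` list: `R1`, `k2`, `bp_nd`, `k2a`, `wrss`,
#'   `converged`, `on_boundary`, `basis_index`.
#' @export
fit_srtm <- function(target, ref, schedule = NULL,
                     k2a_grid = exp(seq(log(0.006), log(0.6), length.out = 128)),
                     dt_s = 1, refine = TRUE) {
  basis <- if (inherits(ref, "srtm_basis")) {
    ref
  } else {
    if (is.null(schedule)) stop("`schedule` is required when `ref` is a TAC")
    srtm_basis(ref, schedule, k2a_grid = k2a_grid, dt_s = dt_s)
  }
  schedule <- basis$schedule
  y <- as.numeric(target)
  if (length(y) != nrow(schedule)) stop("target TAC does not match the schedule")
  if (all(abs(y) < .Machine$double.eps) || all(abs(basis$ref_frames) < .Machine$double.eps)) {
    stop("degenerate input: all-zero target or reference TAC")
  }
  w <- schedule$dur_s / sum(schedule$dur_s)
  x1 <- basis$ref_frames
  fits <- lapply(seq_along(basis$k2a_grid), function(j) wls2(y, x1, basis$B[, j], w))
  wrss <- vapply(fits, `[[`, numeric(1), "wrss")
  j <- which.min(wrss)
  on_boundary <- j == 1L || j == length(basis$k2a_grid)
  if (on_boundary) {
    warning("best SRTM fit on the k2a grid boundary; widen the grid")
  }
  best_k2a <- basis$k2a_grid[j]
  best <- fits[[j]]
  if (refine && !on_boundary) {
    grid <- basis$grid
    obj <- function(logk2a) {
      k2a <- exp(logk2a)
      Bk <- frame_average(conv_exp(basis$cr_fine, k2a, grid$dt_min),
                          schedule, grid)
      wls2(y, x1, Bk, w)$wrss
    }
    opt <- stats::optimize(obj, interval = log(basis$k2a_grid[c(j - 1L, j + 1L)]),
                           tol = 1e-6)
    if (opt$objective <= best$wrss) {
      best_k2a <- exp(opt$minimum)
      Bk <- frame_average(conv_exp(basis$cr_fine, best_k2a, basis$grid$dt_min),
                          schedule, basis$grid)
      best <- wls2(y, x1, Bk, w)
    }
  }
  R1 <- best$theta[1]
  k2 <- best$theta[2] + R1 * best_k2a
  structure(list(
    R1 = R1, k2 = k2, bp_nd = k2 / best_k2a - 1, k2a = best_k2a,
    wrss = best$wrss, converged = is.finite(best$wrss) && !on_boundary,
    on_boundary = on_boundary, basis_index = j
  ), class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf("<srtm_fit> R1 = %.4f, k2 = %.4f /min, BP_ND = %.4f, k2a = %.4f /min%s\n",
              x$R1, x$k2, x$bp_nd, x$k2a,
              if (x$on_boundary) " [grid boundary]" else ""))
  invisible(x)
}
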