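#' Parametric plasma input function
#'
#' Tri-exponential model with a linear ramp on the fastest component
#' (Feng-type), used only to generate realistic reference-region TACs for
#' simulation; the quantification pipeline itself never sees plasma data.
#' For `t > delta` the concentration is
#' `(A1*(t-delta) - A2 - A3) * exp(l1*(t-delta)) + A2*exp(l2*(t-delta)) +
#'  A3*exp(l3*(t-delta))`, and 0 before arrival. The model is continuous
#' at onset (value 0 at `t = delta`).
#'
#' @param delta arrival delay (min).
#' @param A1 ramp amplitude (activity units per min).
#' @param A2,A3 exponential amplitudes (activity units).
#' @param l1,l2,l3 eigenvalues (1/min), `l1 < l2 < l3 < 0`.
#' @return An `input_function` parameter list.
#' @export
input_function <- function(delta = 0.7, A1 = 851.1, A2 = 5, A3 = 5,
                           l1 = -4.1339, l2 = -0.25, l3 = -0.04) {
  p <- list(delta = delta, A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    stop("input function parameters must be finite scalars")
  }
  if (!(l1 < l2 && l2 < l3 && l3 < 0)) {
    stop("eigenvalues must satisfy l1 < l2 < l3 < 0")
  }
  structure(p, class = "input_function")
}

#' Evaluate the plasma input function
#'
#' @param t time(s) in minutes, `t >= 0`; vectorised.
#' @param p an [input_function()] parameter set.
#' @return concentration at each `t` (0 before tracer arrival).
#' @export
input_function_value <- function(t, p = input_function()) {
  if (!inherits(p, "input_function")) p <- do.call(input_function, as.list(p))
  if (any(t < 0)) stop("t must be non-negative")
  tt <- t - p$delta
  v <- ifelse(tt <= 0, 0,
              (p$A1 * tt - p$A2 - p$A3) * exp(p$l1 * tt) +
                p$A2 * exp(p$l2 * tt) + p$A3 * exp(p$l3 * tt))
  v
}
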