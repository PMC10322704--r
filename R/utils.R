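# Internal numeric helpers shared across modules.

pc_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pupilcoding_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' z-score a trace
#'
#' Subtracts the mean and divides by the standard deviation (denominator
#' `n - 1`). Errors on zero-variance input rather than returning NaN.
#'
#' @param x Numeric vector.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    pc_stop("cannot z-score a zero-variance trace", "pc_zero_variance")
  }
  (x - mean(x)) / s
}

# z-score that maps a constant trace to zeros instead of failing; used by the
# generator where a predictor may be legitimately absent (e.g. no running).
zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Sample times for a trace of `duration_s` seconds at `rate_hz`; the first
# sample sits at t = 0 and the last strictly before `duration_s`.
clock <- function(duration_s, rate_hz) {
  n <- floor(duration_s * rate_hz)
  (seq_len(n) - 1) / rate_hz
}

#' Resample a trace onto a new time base
#'
#' Linear interpolation; queries outside the source support are held at the
#' nearest value. This is the single alignment rule used everywhere traces
#' are moved between the pupil and imaging clocks.
#'
#' @param time_from,values Source trace.
#' @param time_to Target sample times.
#' @return Values at `time_to`.
#' @export
resample_linear <- function(time_from, values, time_to) {
  stats::approx(time_from, values, xout = time_to, rule = 2)$y
}

#' First-order low-pass filter
#'
#' Discrete one-pole filter `y[i] = a*y[i-1] + (1-a)*x[i]` with
#' `a = exp(-dt/tau_s)`, initialised at `x[1]` so a constant input passes
#' through unchanged. A step input approaches its asymptote as
#' `1 - exp(-t/tau_s)`.
#'
#' @param x Numeric input trace.
#' @param dt Sample interval in seconds.
#' @param tau_s Time constant in seconds; `tau_s <= 0` returns `x` unchanged.
#' @return Filtered trace, same length as `x`.
#' @export
lowpass1 <- function(x, dt, tau_s) {
  if (tau_s <= 0) return(x)
  a <- exp(-dt / tau_s)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive", init = x[1]))
}

#' Causal convolution
#'
#' Convolves `x` with kernel `k` and truncates to `length(x)`, so sample `t`
#' of the output depends only on `x[1..t]` (kernel sample 1 applies at lag 0).
#'
#' @param x Numeric vector.
#' @param k Numeric kernel.
#' @return Numeric vector, same length as `x`.
#' @export
conv_causal <- function(x, k) {
  stats::convolve(x, rev(k), type = "open")[seq_along(x)]
}

#' Exponential calcium-indicator kernel
#'
#' Single-exponential decay kernel emulating a slow indicator such as
#' GCaMP6s, normalised to unit sum so the DC gain is 1.
#'
#' @param tau_s Decay time constant in seconds; `tau_s <= 0` gives the
#'   identity kernel (a single 1).
#' @param dt Sample interval in seconds.
#' @return Numeric kernel vector.
#' @export
calcium_kernel <- function(tau_s, dt) {
  if (tau_s <= 0) return(1)
  t <- seq(0, 6 * tau_s, by = dt)
  k <- exp(-t / tau_s)
  k / sum(k)
}
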