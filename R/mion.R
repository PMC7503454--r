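#' MION impulse response kernel
#'
#' The intravascular contrast agent MION tracks cerebral blood volume, so
#' activation *decreases* the measured signal. The impulse response is modeled
#' as a sign-inverted gamma-variate,
#' `h(t) = -(t/d)^a exp(a (1 - t/d))` (peak at `t = d`), optionally minus a
#' delayed positive rebound, and is normalized so that the response to a
#' sustained unit boxcar asymptotes to -1. The kernel is causal: it is zero
#' for `t <= 0`.
#'
#' @param peak_delay_s Time to (negative) peak, seconds; must be positive.
#' @param undershoot_ratio Amplitude of a positive rebound lobe (same shape,
#'   peak at twice the delay) relative to the main lobe; default 0.
#' @param dt_s Sampling interval of the kernel, seconds. Convolution of TR-
#'   sampled regressors requires `dt_s` equal to the TR.
#' @param duration_s Kernel support; default eight peak delays.
#' @param shape Gamma-variate dispersion exponent `a` (larger = narrower).
#' @return Object of class `mion_kernel`: `times`, `amplitudes`, `dt_s`.
#' @examples
#' k <- mion_irf()
#' sum(k$amplitudes)  # -1: sustained boxcar plateaus at -1
#' @export
mion_irf <- function(peak_delay_s = 10, undershoot_ratio = 0, dt_s = 2.5,
                     duration_s = 8 * peak_delay_s, shape = 3) {
  if (!is.numeric(peak_delay_s) || peak_delay_s <= 0) {
    stop("peak_delay_s must be positive")
  }
  stopifnot(dt_s > 0, duration_s > peak_delay_s, shape > 0,
            undershoot_ratio >= 0, undershoot_ratio < 1)
  t <- seq(dt_s, duration_s, by = dt_s)
  gv <- function(tt, d) ifelse(tt <= 0, 0, (tt / d)^shape * exp(shape * (1 - tt / d)))
  h <- gv(t, peak_delay_s) - undershoot_ratio * gv(t, 2 * peak_delay_s)
  h <- -h / sum(h)  # boxcar response plateaus at -1
  structure(list(times = t, amplitudes = h, dt_s = dt_s,
                 peak_delay_s = peak_delay_s,
                 undershoot_ratio = undershoot_ratio, shape = shape),
            class = "mion_kernel")
}

#' Convolve a TR-sampled regressor with a MION kernel
#'
#' @param x Numeric regressor sampled at the kernel's `dt_s`.
#' @param kernel A [mion_irf()] kernel.
#' @return Convolved regressor, truncated to `length(x)`.
#' @export
mion_convolve <- function(x, kernel) {
  stopifnot(inherits(kernel, "mion_kernel"))
  convolve_causal(x, kernel$amplitudes)
}

#' @export
print.mion_kernel <- function(x, ...) {
  cat(sprintf("<mion_kernel> peak %gs, dt %gs, %d samples, min %.4f\n",
              x$peak_delay_s, x$dt_s, length(x$amplitudes),
              min(x$amplitudes)))
  invisible(x)
}
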