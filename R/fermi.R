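# Fermi impulse response and the forward convolution model shared by the
# tissue-curve generator and the deconvolution fitter. Units: myocardial
# blood flow (MBF) is carried in mL/min/g; the impulse response is sampled
# per second, so its plateau amplitude is MBF / 60.

#' Fermi impulse response
#'
#' `h(t) = (mbf/60) * (1 + exp(-w/k)) / (1 + exp((t - delay - w) / k))` for
#' `t >= delay` and 0 before. The plateau value at `t = delay` equals
#' `mbf / 60` (per-second units), so the fitted plateau amplitude reads out
#' myocardial blood flow directly in mL/min/g.
#'
#' @param times Sample times (s).
#' @param mbf Myocardial blood flow (mL/min/g), >= 0.
#' @param k_s Width (decay steepness) parameter (s), > 0.
#' @param w_s Shoulder (plateau duration) parameter (s), >= 0.
#' @param delay_s Bolus arrival delay of the tissue response (s), >= 0.
#' @return Impulse response sampled at `times`, units 1/s scaled by MBF.
#' @export
fermi_ir <- function(times, mbf, k_s, w_s, delay_s = 0) {
  if (mbf < 0) cmr_invalid("mbf must be >= 0")
  if (k_s <= 0) cmr_invalid("Fermi width k_s must be > 0")
  a <- (mbf / 60) * (1 + exp(-w_s / k_s))
  h <- a / (1 + exp((times - delay_s - w_s) / k_s))
  h[times < delay_s] <- 0
  h
}

#' Discrete causal convolution of an input curve with an impulse response
#'
#' `out[i] = dt * sum_{j=1..i} input[j] * ir[i - j + 1]` — the Riemann
#' approximation of the convolution integral on a uniform grid. This is the
#' forward model of the tissue curve: tissue = AIF (*) h.
#'
#' @param input Input curve (e.g. the AIF) on a uniform grid.
#' @param ir Impulse response sampled on the same grid.
#' @param dt Sampling interval (s).
#' @return Convolved curve, same length as `input`.
#' @export
convolve_ir <- function(input, ir, dt) {
  n <- length(input)
  if (length(ir) != n) cmr_invalid("input and impulse response lengths differ")
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(input[seq_len(i)] * ir[i:1])
  }
  out * dt
}

#' Generate a phantom tissue curve from the AIF and a true flow
#'
#' Builds the tissue signal-intensity curve as the convolution of the AIF
#' with a Fermi impulse response whose plateau amplitude encodes
#' `true_mbf`, then (optionally) adds Gaussian noise. Deconvolving the
#' noise-free curve against the same AIF recovers `true_mbf` (closure).
#'
#' @param aif AIF as returned by [generate_aif()] (list with `time`,
#'   `signal`) or a plain numeric vector (then `dt` must be given).
#' @param true_mbf True myocardial blood flow (mL/min/g), >= 0.
#' @param fermi_shape List with `k_s`, `w_s`, `delay_s` (see [fermi_ir()]).
#' @param noise_sd Additive Gaussian noise SD (signal-intensity units).
#' @param dt Sampling interval (s); taken from `aif$time` when omitted.
#' @return Numeric tissue curve of the same length as the AIF.
#' @export
generate_tissue_curve <- function(aif, true_mbf,
                                  fermi_shape = list(k_s = 2, w_s = 8,
                                                     delay_s = 1),
                                  noise_sd = 0, dt = NULL) {
  if (is.list(aif)) {
    dt <- dt %||% (aif$time[2L] - aif$time[1L])
    sig <- aif$signal
  } else {
    if (is.null(dt)) cmr_invalid("dt required when aif is a bare vector")
    sig <- aif
  }
  if (true_mbf < 0) cmr_invalid("true_mbf must be >= 0")
  n <- length(sig)
  times <- (seq_len(n) - 1L) * dt
  h <- fermi_ir(times, true_mbf, fermi_shape$k_s, fermi_shape$w_s,
                fermi_shape$delay_s %||% 0)
  tissue <- convolve_ir(sig, h, dt)
  if (noise_sd > 0) tissue <- tissue + rnorm(n, sd = noise_sd)
  tissue
}
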