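# First-pass arterial input function: a gamma-variate bolus with an
# additive delayed, scaled recirculation copy. Normalised so the
# gamma-variate peaks at `amplitude` exactly at t = onset + shape * scale.

#' Gamma-variate bolus curve
#'
#' `amplitude * ((t - onset) / (shape * scale))^shape *
#'  exp(shape - (t - onset) / scale)` for `t > onset`, 0 before. The curve
#' attains its maximum `amplitude` at `t = onset + shape * scale`.
#'
#' @param t Time points (s).
#' @param amplitude Peak value (signal-intensity units).
#' @param onset Bolus arrival time (s).
#' @param shape,scale Dimensionless shape and time scale (s) of the
#'   gamma-variate; both must be positive.
#' @return Numeric vector of curve values at `t`.
#' @export
gamma_variate <- function(t, amplitude, onset, shape, scale) {
  if (shape <= 0 || scale <= 0) cmr_invalid("shape and scale must be > 0")
  x <- (t - onset) / scale
  y <- numeric(length(t))
  pos <- x > 0
  y[pos] <- amplitude * (x[pos] / shape)^shape * exp(shape - x[pos])
  y
}

#' Generate the phantom arterial input function
#'
#' Samples the gamma-variate first pass plus a recirculation bump (a copy
#' delayed by `recirc_delay_s`, scaled by `recirc_fraction`, optionally
#' broadened) on the config's frame grid. The curve is zero during the
#' pre-contrast frames and non-negative everywhere.
#'
#' @param config A [phantom_config()].
#' @return List with `time` (s) and `signal` vectors of length `n_frames`.
#' @examples
#' aif <- generate_aif(phantom_config())
#' which.max(aif$signal)  # first-pass peak before the recirculation bump
#' @export
generate_aif <- function(config) {
  validate_phantom_config(config)
  ap <- config$aif_params
  t <- (seq_len(config$n_frames) - 1L) * config$frame_interval_s
  first <- gamma_variate(t, ap$amplitude, ap$onset_s, ap$shape, ap$scale_s)
  broad <- ap$recirc_broadening %||% 1
  recirc <- ap$recirc_fraction *
    gamma_variate(t, ap$amplitude, ap$onset_s + ap$recirc_delay_s,
                  ap$shape, ap$scale_s * broad)
  list(time = t, signal = first + recirc)
}
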