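#' Low-pass filter specification
#'
#' The displacement-to-acceleration chain uses a 30 Hz low-pass applied with
#' zero-phase forward-backward filtering, re-applied after each
#' differentiation step to suppress the high-frequency noise that
#' differentiation amplifies. The filter family/order are configurable; the
#' default is a 4th-order Butterworth (maximally flat passband over the
#' sub-30 Hz physiological band; forward-backward application doubles the
#' effective order and cancels the phase).
#'
#' @param cutoff cutoff frequency in Hz (default 30).
#' @param order filter order (default 4, minimum 2).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 30, order = 4) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    cape_stop("cutoff must be positive", "cape_config_error")
  if (order < 2) cape_stop("filter order must be >= 2", "cape_config_error")
  structure(list(cutoff = cutoff, order = as.integer(order)),
            class = "filter_spec")
}

#' Zero-phase low-pass filtering
#'
#' Applies the Butterworth low-pass of `spec` forward and backward
#' (`signal::filtfilt`), giving zero group delay: a symmetric pulse keeps its
#' peak sample. Output length equals input length.
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered series, same length as `x`.
#' @export
zero_phase_lowpass <- function(x, fs, spec = filter_spec()) {
  if (spec$cutoff >= fs / 2)
    cape_stop(sprintf("cutoff %g Hz is not below Nyquist (%g Hz)",
                      spec$cutoff, fs / 2), "cape_config_error")
  if (length(x) <= 3 * spec$order)
    cape_stop("signal too short for the requested filter order",
              "cape_input_error")
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Numerical differentiation
#'
#' Central differences scaled by the sampling rate (units per second), with
#' one-sided differences at the two endpoints so the output has the same
#' length as the input and no added delay.
#'
#' @param x numeric time series (length >= 3).
#' @param fs sampling rate in Hz.
#' @return the first derivative of `x`, same length.
#' @export
differentiate <- function(x, fs) {
  n <- length(x)
  if (n < 3) cape_stop("differentiate needs at least 3 samples",
                       "cape_input_error")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# filter -> differentiate -> filter -> differentiate -> filter, one channel
acceleration_chain <- function(x, fs, spec) {
  y <- zero_phase_lowpass(x, fs, spec)
  y <- differentiate(y, fs)
  y <- zero_phase_lowpass(y, fs, spec)
  y <- differentiate(y, fs)
  zero_phase_lowpass(y, fs, spec)
}

#' Convert a displacement recording to acceleration
#'
#' Per channel: low-pass, differentiate, low-pass, differentiate, low-pass
#' (the filter is re-applied after each derivative). The acceleration signal
#' sharpens the pulse-arrival feature and suppresses baseline motion drift,
#' which is why fiducial points are defined on it. Metadata (fs, site map,
#' geometry) is propagated unchanged; no samples are trimmed.
#'
#' @param rec a displacement `ldv_recording`.
#' @param spec a [filter_spec()].
#' @return an `ldv_recording` with `units = "acceleration"`.
#' @export
displacement_to_acceleration <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "ldv_recording"))
  acc <- rec
  acc$channels <- t(apply(rec$channels, 1, acceleration_chain,
                          fs = rec$fs, spec = spec))
  acc$units <- "acceleration"
  acc
}
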