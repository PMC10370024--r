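#' Zero-phase Butterworth filter
#'
#' Third-order (by default) Butterworth low- or high-pass, applied forward
#' and backward so the net filter has zero phase and the squared single-pass
#' magnitude response. Edge transients are controlled by reflection padding
#' (odd extension) before the two passes, as is standard for zero-phase
#' filtering of finite ERP segments.
#'
#' @param waveform numeric vector.
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff_hz cutoff frequency, 0 < cutoff < Nyquist.
#' @param fs sampling rate (Hz).
#' @param order filter order of the single pass.
#' @return filtered vector of the same length.
#' @export
butterworth_filter <- function(waveform, kind = c("lowpass", "highpass"),
                               cutoff_hz, fs, order = 3L) {
  kind <- match.arg(kind)
  if (!all(is.finite(waveform))) stop("waveform contains non-finite values")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %g Hz not in (0, Nyquist = %g Hz)", cutoff_hz, fs / 2))
  bf <- signal::butter(order, 2 * cutoff_hz / fs,
                       type = if (kind == "lowpass") "low" else "high")
  filtfilt_reflect(bf$b, bf$a, waveform)
}

# forward-backward IIR filtering with odd reflection padding; full-length
# reflection keeps startup transients of low-cutoff filters (long impulse
# responses) out of the returned segment
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  npad <- n - 1L
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[npad + seq_len(n)]
}

#' Analytic two-pass Butterworth magnitude response
#'
#' `|H(f)|^2 = 1 / (1 + (f/fc)^(2*order))` for a low-pass (reciprocal ratio
#' for a high-pass): the amplitude ratio a sinusoid retains after the
#' forward-backward filter, used as the oracle for the filter contract.
#'
#' @param f probe frequency (Hz).
#' @param cutoff_hz cutoff (Hz).
#' @param order single-pass order.
#' @param kind `"lowpass"` or `"highpass"`.
#' @return the two-pass amplitude ratio.
#' @export
butterworth_gain2 <- function(f, cutoff_hz, order = 3L,
                              kind = c("lowpass", "highpass")) {
  kind <- match.arg(kind)
  r <- if (kind == "lowpass") f / cutoff_hz else cutoff_hz / f
  1 / (1 + r^(2 * order))
}

#' Decimate a waveform to a lower sampling rate
#'
#' Anti-alias low-pass (Butterworth order 6 at 80% of the target Nyquist,
#' zero-phase) followed by integer subsampling. The target rate must divide
#' the input rate.
#'
#' @param waveform numeric vector.
#' @param fs input sampling rate (Hz).
#' @param target_fs output rate (Hz).
#' @return list `x` (decimated signal) and `fs`.
#' @export
decimate_wave <- function(waveform, fs, target_fs) {
  if (target_fs > fs) stop("downsample target above input rate")
  if (target_fs == fs) return(list(x = waveform, fs = fs))
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("target rate must divide the input rate")
  y <- butterworth_filter(waveform, "lowpass", 0.8 * target_fs / 2, fs, order = 6L)
  list(x = y[seq(1, length(y), by = round(factor))], fs = target_fs)
}
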