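#' Binomial reduced interference distribution
#'
#' Discrete Cohen-class time-frequency energy transform: the local
#' autocorrelation `x(n+m+tau) x(n+m-tau)` is smoothed along time at each
#' lag `tau` with normalized binomial weights of order `2*tau` (the binomial
#' RID kernel, which suppresses cross-terms while leaving the lag-0 line —
#' and hence the signal energy — untouched), then Fourier-transformed over
#' lag. The transform operates on the real signal; the alias-free frequency
#' range of a real-signal Cohen-class distribution extends to a quarter of
#' the sampling rate, so the surface reports `0 .. fs/4` with the mirrored
#' negative-frequency content folded in. Normalization satisfies the energy
#' contract `sum(values) == sum(x^2)` exactly up to float rounding.
#'
#' @param waveform finite numeric vector.
#' @param fs sampling rate (Hz).
#' @param n_freq_bins number of frequency bins covering `0..fs/4`
#'   (FFT length over lag is `2*(n_freq_bins-1)`).
#' @param max_lag largest autocorrelation lag in samples (default: largest
#'   that both the signal and the FFT length admit).
#' @param downsample_to optional target rate (Hz); the waveform is
#'   anti-alias decimated first and the contract then applies to the
#'   decimated signal.
#' @param time_ms optional time axis of the input, carried to the surface.
#' @return a `tf_surface`: list with `values` (time x frequency matrix,
#'   possibly signed cells), `time_ms`, `freq_hz`, `fs`, `input_energy`.
#' @export
binomial_rid <- function(waveform, fs, n_freq_bins = 65L, max_lag = NULL,
                         downsample_to = NULL, time_ms = NULL) {
  if (!all(is.finite(waveform))) stop("waveform contains non-finite values")
  if (is.null(time_ms)) time_ms <- (seq_along(waveform) - 1) / fs * 1000
  if (!is.null(downsample_to)) {
    dec <- decimate_wave(waveform, fs, downsample_to)
    keep <- seq(1, length(waveform), by = round(fs / downsample_to))
    time_ms <- time_ms[keep]
    waveform <- dec$x
    fs <- dec$fs
  }
  n <- length(waveform)
  mfft <- 2L * (as.integer(n_freq_bins) - 1L)
  if (mfft < 2L) stop("n_freq_bins must be >= 2")
  lag_cap <- (mfft - 2L) %/% 2L
  if (is.null(max_lag)) max_lag <- min(lag_cap, (n - 1L) %/% 2L)
  max_lag <- as.integer(max_lag)
  if (max_lag > lag_cap)
    stop("max_lag too large for n_freq_bins (needs 2*max_lag+1 <= FFT length)")
  if (n < 2L * max_lag) stop("waveform shorter than twice the maximum lag")

  K <- rid_lag_matrix(as.numeric(waveform), max_lag)   # n x (L+1)
  A <- matrix(0, mfft, n)
  A[1, ] <- K[, 1]
  if (max_lag >= 1) for (tau in seq_len(max_lag)) {
    A[tau + 1, ] <- K[, tau + 1]
    A[mfft - tau + 1, ] <- K[, tau + 1]
  }
  Fm <- Re(stats::mvfft(A))                            # real: A even in lag
  half <- mfft %/% 2L
  folded <- rbind(Fm[1, , drop = FALSE],
                  2 * Fm[1 + seq_len(half - 1L), , drop = FALSE],
                  Fm[half + 1L, , drop = FALSE]) / mfft
  structure(list(values = t(folded),
                 time_ms = time_ms,
                 freq_hz = (0:half) * fs / (2 * mfft),
                 fs = fs,
                 input_energy = sum(waveform^2)),
            class = "tf_surface")
}

#' Crop a time-frequency surface to an analysis window
#'
#' @param surface a `tf_surface`.
#' @param window_ms two-element ms interval (closed).
#' @return the cropped `tf_surface`.
#' @export
crop_surface <- function(surface, window_ms) {
  keep <- surface$time_ms >= window_ms[1] & surface$time_ms <= window_ms[2]
  if (!any(keep)) stop("crop window contains no time bins")
  surface$values <- surface$values[keep, , drop = FALSE]
  surface$time_ms <- surface$time_ms[keep]
  surface
}

#' Band configuration for ERP time-frequency decomposition
#'
#' Delta uses a low-pass pre-filter, theta a high-pass (third order,
#' zero-phase), letting the subsequent PCA define the band boundary.
#'
#' @param delta_cutoff_hz,theta_cutoff_hz Butterworth cutoffs.
#' @param order single-pass filter order.
#' @param downsample_to analysis rate for the RID (Hz; NULL disables).
#' @param n_freq_bins frequency bins over `0..rate/4`.
#' @param crop_ms analysis window of the surfaces.
#' @return list of class `band_config`.
#' @export
band_config <- function(delta_cutoff_hz = 4, theta_cutoff_hz = 2, order = 3L,
                        downsample_to = 128, n_freq_bins = 65L,
                        crop_ms = c(-500, 1000)) {
  structure(list(delta_cutoff_hz = delta_cutoff_hz,
                 theta_cutoff_hz = theta_cutoff_hz, order = order,
                 downsample_to = downsample_to, n_freq_bins = n_freq_bins,
                 crop_ms = crop_ms), class = "band_config")
}

#' Band-filtered time-frequency surfaces of condition ERPs
#'
#' For each band (delta via low-pass, theta via high-pass), each subject,
#' condition and EEG channel: pre-filter the ERP waveform, decimate,
#' transform with [binomial_rid()], and crop to the analysis window.
#'
#' @param erps an `erp_set` (from [average_erp()]) or a list of them (one
#'   per subject).
#' @param config a [band_config()].
#' @param channels channel names to transform (default: all EEG channels).
#' @param which_bands bands to compute (subset of `c("delta", "theta")`).
#' @return named list `delta`/`theta` of `tf_stack` objects: `values`
#'   array `[row, time, freq]`, `index` data.frame (subject, condition,
#'   channel), `time_ms`, `freq_hz`, `band`.
#' @export
erp_band_surfaces <- function(erps, config = band_config(), channels = NULL,
                              which_bands = c("delta", "theta")) {
  if (inherits(erps, "erp_set")) erps <- list(erps)
  bands <- list(delta = list(kind = "lowpass", cutoff = config$delta_cutoff_hz),
                theta = list(kind = "highpass", cutoff = config$theta_cutoff_hz))
  bands <- bands[match.arg(which_bands, several.ok = TRUE)]
  out <- list()
  for (bn in names(bands)) {
    rows <- list(); idx <- list(); axes <- NULL
    for (es in erps) {
      if (nrow(es$erp) < 2L)
        stop("ERPs for both conditions are required (subject ",
             es$subject_id, ")")
      chn <- channels
      if (is.null(chn)) chn <- es$montage$name[es$montage$type == "eeg"]
      for (cond in rownames(es$erp)) for (ch in chn) {
        w <- butterworth_filter(es$erp[cond, ch, ], bands[[bn]]$kind,
                                bands[[bn]]$cutoff, es$sampling_rate,
                                config$order)
        sf <- binomial_rid(w, es$sampling_rate,
                           n_freq_bins = config$n_freq_bins,
                           downsample_to = config$downsample_to,
                           time_ms = es$time_ms)
        sf <- crop_surface(sf, config$crop_ms)
        rows[[length(rows) + 1]] <- sf$values
        idx[[length(idx) + 1]] <- data.frame(
          subject = es$subject_id, condition = cond, channel = ch,
          stringsAsFactors = FALSE)
        if (is.null(axes)) axes <- sf[c("time_ms", "freq_hz")]
      }
    }
    values <- array(0, dim = c(length(rows), dim(rows[[1]])))
    for (i in seq_along(rows)) values[i, , ] <- rows[[i]]
    out[[bn]] <- structure(list(values = values,
                                index = do.call(rbind, idx),
                                time_ms = axes$time_ms,
                                freq_hz = axes$freq_hz,
                                band = bn),
                           class = "tf_stack")
  }
  out
}

#' @export
print.tf_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tf_stack %s: %d rows x %d time bins x %d freq bins (%g..%g ms, %g..%g Hz)>\n",
              x$band, d[1], d[2], d[3], min(x$time_ms), max(x$time_ms),
              min(x$freq_hz), max(x$freq_hz)))
  invisible(x)
}
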