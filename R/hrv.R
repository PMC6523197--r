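# HRV feature extraction: band-pass + R-peak detection, interval cleaning,
# cubic-spline resampling to an even grid, Blackman-windowed averaged
# periodogram, and LF/HF band power integration.

#' Detect R peaks in an ECG recording
#'
#' Band-pass filters the signal (0.05-40 Hz), then applies a
#' derivative-square-moving-window-integration detector with an adaptive
#' threshold and a 250 ms refractory period; candidate peaks are refined to
#' the local maximum of the filtered signal within +/- 100 ms.
#'
#' @param ecg A `raw_signal` (channel ECG), at least 240 s long.
#' @return Numeric vector of strictly increasing beat times, s.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "raw_signal"), ecg$channel == "ECG")
  fs <- ecg$fs
  if (length(ecg$samples) / fs < 240)
    stop("detect_r_peaks: need at least 240 s of ECG")
  bp <- signal::butter(2, c(0.05, 40) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, ecg$samples)
  # derivative -> square -> moving-window integration (~150 ms)
  d <- c(0, diff(xf)) * fs
  sq <- d^2
  wlen <- max(3L, round(0.15 * fs))
  cs <- cumsum(c(0, sq))
  half_w <- wlen %/% 2L
  nn <- length(sq)
  lo <- pmax(0L, seq_len(nn) - half_w - 1L)
  hi_i <- pmin(nn, seq_len(nn) + half_w)
  mwi <- (cs[hi_i + 1L] - cs[lo + 1L]) / wlen
  thr <- 0.25 * stats::quantile(mwi, 0.98)
  if (thr <= 0) stop("detect_r_peaks: signal quality too low (flat signal)")
  above <- mwi > thr
  # rising edges of the supra-threshold regions
  edges <- which(diff(c(FALSE, above)) == 1)
  half <- round(0.1 * fs)
  refract <- 0.25
  n <- length(xf)
  peaks <- numeric(0)
  for (e in edges) {
    i0 <- max(1L, e - half); i1 <- min(n, e + half)
    p <- i0 + which.max(xf[i0:i1]) - 1L
    tp <- (p - 1) / fs
    if (length(peaks) == 0L || tp - peaks[length(peaks)] > refract)
      peaks <- c(peaks, tp)
  }
  if (length(peaks) < 60)
    stop("detect_r_peaks: fewer than 60 beats detected; signal quality error")
  peaks
}

#' Evenly resample the RR interval series
#'
#' Pairs each interval with the time of its closing beat, removes
#' physiologically implausible intervals (outside 250-3000 ms, the automatic
#' stand-in for manual beat inspection), and cubic-spline interpolates onto
#' an even grid.
#'
#' @param beat_times Strictly increasing beat times, s (or an `rr_series`).
#' @param resample_fs Target rate for the even grid, Hz.
#' @return An `rr_series` with the `uniform` field set (list with `t`,
#'   `rr_ms`, `fs`).
#' @export
uniform_rr <- function(beat_times, resample_fs = 4) {
  if (inherits(beat_times, "rr_series")) beat_times <- beat_times$beat_times
  if (length(beat_times) < 4) stop("uniform_rr: need at least 4 beats")
  rr <- diff(beat_times) * 1000
  tt <- beat_times[-1]
  ok <- rr > 250 & rr < 3000
  if (!any(ok)) stop("uniform_rr: all intervals outside the valid range")
  rr <- rr[ok]; tt <- tt[ok]
  if (length(rr) < 4) stop("uniform_rr: too few valid intervals")
  grid <- seq(beat_times[1], beat_times[length(beat_times)],
              by = 1 / resample_fs)
  u <- stats::spline(tt, rr, xout = grid, method = "fmm")$y
  rr_series(beat_times,
            uniform = list(t = grid, rr_ms = u, fs = resample_fs))
}

#' Averaged Blackman-windowed spectrum of the uniform RR series
#'
#' @param rr An `rr_series` with the uniform field set (see [uniform_rr()]),
#'   or the uniform list itself.
#' @param window_len Segment length, samples.
#' @param overlap_frac Fractional segment overlap.
#' @return List of class `hrv_spectrum`: `freqs` (Hz), `psd` (ms^2/Hz),
#'   `window_len`, `n_segments`.
#' @export
averaged_spectrum <- function(rr, window_len = 256, overlap_frac = 0.5) {
  u <- if (inherits(rr, "rr_series")) rr$uniform else rr
  if (is.null(u)) stop("averaged_spectrum: run uniform_rr() first")
  sp <- welch_psd(u$rr_ms, fs = u$fs, window_len = window_len,
                  overlap_frac = overlap_frac)
  structure(sp, class = "hrv_spectrum")
}

#' HRV band indices from an averaged spectrum
#'
#' Trapezoidal integration of the spectral density over the LF, HF and
#' total-power bands; normalized indices divide by the total-band power.
#'
#' @param spec An `hrv_spectrum`.
#' @param bands A [spectral_bands()] object.
#' @return List of class `hrv_indices`: `HRVLF`, `HRVHF` (ms^2), `HRVLFn`,
#'   `HRVHFn` (normalized units), `total_power` (ms^2), and the band limits
#'   used.
#' @export
hrv_band_indices <- function(spec, bands = spectral_bands()) {
  stopifnot(inherits(spec, "hrv_spectrum"))
  lf <- band_power(spec$freqs, spec$psd, bands$lf)
  hf <- band_power(spec$freqs, spec$psd, bands$hf)
  tp <- band_power(spec$freqs, spec$psd, bands$tp)
  if (tp <= 0)
    stop("hrv_band_indices: zero total power; normalization undefined")
  structure(list(HRVLF = lf, HRVHF = hf,
                 HRVLFn = lf / tp, HRVHFn = hf / tp,
                 total_power = tp,
                 bands = list(lf = bands$lf, hf = bands$hf, tp = bands$tp)),
            class = "hrv_indices")
}

#' All four HRV indices from a raw ECG recording
#'
#' Convenience wrapper: R-peak detection, interval cleaning and 4 Hz spline
#' resampling, 256-point Blackman averaged spectrum, band integration.
#'
#' @param ecg A `raw_signal` (ECG).
#' @param bands A [spectral_bands()].
#' @param resample_fs RR resampling rate, Hz.
#' @return An `hrv_indices` list.
#' @export
hrv_features <- function(ecg, bands = spectral_bands(), resample_fs = 4) {
  beats <- detect_r_peaks(ecg)
  rr <- uniform_rr(beats, resample_fs = resample_fs)
  hrv_band_indices(averaged_spectrum(rr), bands = bands)
}
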