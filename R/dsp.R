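# Shared DSP primitives: Welch/Blackman averaged periodogram, band
# integration, analytic signal, and zero-phase FFT-mask low-pass used by the
# complex demodulation bank.

#' Averaged modified periodogram (Welch, Blackman window)
#'
#' Splits the series into overlapping segments, removes each segment's mean,
#' applies a Blackman window, and averages the one-sided periodograms. The
#' window-power normalization makes the integrated density approximate the
#' series variance (Parseval).
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param window_len Segment length in samples.
#' @param overlap_frac Fractional overlap between consecutive segments.
#' @return List with `freqs` (Hz), `psd` (x-units^2/Hz), `window_len`,
#'   `n_segments`.
#' @export
welch_psd <- function(x, fs, window_len = 256, overlap_frac = 0.5) {
  n <- length(x)
  if (n < window_len)
    stop("welch_psd: series (", n, ") shorter than one window (",
         window_len, ")")
  step <- max(1L, as.integer(round(window_len * (1 - overlap_frac))))
  starts <- seq.int(1L, n - window_len + 1L, by = step)
  w <- signal::blackman(window_len)
  wpow <- sum(w^2)
  nf <- window_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nf)]
    p <- Mod(X)^2 / (fs * wpow)
    # one-sided: double everything except DC (and Nyquist when present)
    last_double <- if (window_len %% 2L == 0L) nf - 1L else nf
    if (last_double >= 2L) p[2:last_double] <- 2 * p[2:last_double]
    acc <- acc + p
  }
  list(freqs = (seq_len(nf) - 1L) * fs / window_len,
       psd = acc / length(starts),
       window_len = window_len,
       n_segments = length(starts))
}

#' Integrate a power spectral density over a frequency band
#'
#' Trapezoidal integration with linear interpolation at the exact band
#' edges, so the result does not jump as band limits cross grid points.
#'
#' @param freqs Frequency grid, Hz.
#' @param psd Density values on `freqs`.
#' @param band Two-element `(low, high)` in Hz.
#' @return Integrated power (x-units^2).
#' @export
band_power <- function(freqs, psd, band) {
  lo <- max(band[1], freqs[1])
  hi <- min(band[2], freqs[length(freqs)])
  if (hi <= lo) return(0)
  inner <- freqs[freqs > lo & freqs < hi]
  fg <- c(lo, inner, hi)
  pg <- stats::approx(freqs, psd, xout = fg)$y
  pracma::trapz(fg, pg)
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' @param x Real numeric series.
#' @return Complex vector; `Mod()` of it is the instantaneous amplitude.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase low-pass by FFT masking with a raised-cosine transition.
# Works on complex input (asymmetric spectra from complex demodulation).
# cutoff: -6 dB point, Hz; trans: half-width of the cosine rolloff, Hz.
fft_lowpass <- function(x, fs, cutoff, trans = cutoff / 4) {
  n <- length(x)
  f <- (seq_len(n) - 1L)
  f[f > n / 2] <- f[f > n / 2] - n
  f <- abs(f * fs / n)
  H <- ifelse(f <= cutoff - trans, 1,
              ifelse(f >= cutoff + trans, 0,
                     0.5 * (1 + cos(pi * (f - (cutoff - trans)) /
                                      (2 * trans)))))
  y <- stats::fft(stats::fft(x) * H, inverse = TRUE) / n
  if (is.complex(x)) y else Re(y)
}

# Resample a raw_signal to a target rate by linear interpolation (adequate
# for the slow EDA channel; not used for ECG).
resample_signal <- function(x, fs_out) {
  stopifnot(inherits(x, "raw_signal"))
  if (abs(x$fs - fs_out) < 1e-9) return(x)
  n <- length(x$samples)
  t_in <- (seq_len(n) - 1L) / x$fs
  t_out <- seq(0, t_in[n], by = 1 / fs_out)
  raw_signal(stats::approx(t_in, x$samples, xout = t_out)$y,
             fs = fs_out, channel = x$channel, units = x$units)
}
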