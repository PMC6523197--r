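#' Uniformly sampled physiological signal
#'
#' Lightweight container for one channel of uniformly sampled data, the
#' common currency of the simulation and feature-extraction stages.
#'
#' @param samples Numeric vector of samples (mV for ECG, microsiemens for
#'   EDA). Must contain no missing values.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel Either `"ECG"` or `"EDA"`.
#' @param units Unit label carried along for reporting.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(samples, fs, channel = c("ECG", "EDA"),
                       units = NULL) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("raw_signal: samples contain missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("raw_signal: fs must be a positive scalar")
  if (is.null(units)) units <- if (channel == "ECG") "mV" else "uS"
  structure(list(samples = samples, fs = fs, channel = channel,
                 units = units),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %s: %d samples @ %g Hz (%.1f s), units %s\n",
              x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$units))
  invisible(x)
}

#' Duration of a raw signal in seconds
#' @param x A `raw_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "raw_signal"))
  length(x$samples) / x$fs
}

#' Beat-to-beat interval series
#'
#' Holds detected (or simulated) beat times together with the derived
#' inter-beat (RR) intervals and, once computed, the evenly resampled RR
#' series used for spectral analysis.
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @param uniform Optional list with elements `t`, `rr_ms`, `fs` produced by
#'   [uniform_rr()].
#' @return An object of class `rr_series` with fields `beat_times`,
#'   `rr_ms` (length `length(beat_times) - 1`) and `uniform`.
#' @export
rr_series <- function(beat_times, uniform = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L)
    stop("rr_series: need at least two beats")
  if (any(diff(beat_times) <= 0))
    stop("rr_series: beat_times must be strictly increasing")
  structure(list(beat_times = beat_times,
                 rr_ms = diff(beat_times) * 1000,
                 uniform = uniform),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s, mean RR %.0f ms%s\n",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$rr_ms),
              if (is.null(x$uniform)) "" else
                sprintf(", uniform @ %g Hz", x$uniform$fs)))
  invisible(x)
}

#' Spectral analysis bands (Hz)
#'
#' The fixed frequency bands used throughout: HRV low frequency (LF), high
#' frequency (HF) and total power (TP), plus the electrodermal EDASymp and
#' TVSymp bands. Values are conventional for short-term HRV/EDA analysis.
#'
#' @param lf,hf,tp,edasymp,tvsymp Two-element numeric `(low, high)` vectors
#'   in Hz.
#' @return An object of class `spectral_bands`.
#' @export
spectral_bands <- function(lf = c(0.045, 0.15), hf = c(0.15, 0.4),
                           tp = c(0.003, 0.4), edasymp = c(0.045, 0.25),
                           tvsymp = c(0.08, 0.24)) {
  b <- list(lf = lf, hf = hf, tp = tp, edasymp = edasymp, tvsymp = tvsymp)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2L || !is.numeric(v) || v[1] >= v[2])
      stop("spectral_bands: band '", nm, "' must satisfy low < high")
  }
  structure(b, class = "spectral_bands")
}

#' @export
print.spectral_bands <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-8s %.3f-%.3f Hz\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Canonical order of the eight autonomic indices
#'
#' @return Character vector of the eight feature names in canonical order.
#' @export
feature_names <- function() {
  c("SCL", "NS_SCRs", "EDASymp", "TVSymp",
    "HRVLF", "HRVLFn", "HRVHF", "HRVHFn")
}

#' Task condition labels
#' @return Factor levels used for the four conditions.
#' @export
condition_levels <- function() c("BL", "PVT", "NBACK", "SS")

#' Write a raw signal to a two-column CSV
#'
#' @param x A `raw_signal`.
#' @param file Output path; columns are `time_s` and `value`.
#' @export
write_signal_csv <- function(x, file) {
  stopifnot(inherits(x, "raw_signal"))
  n <- length(x$samples)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / x$fs,
                              value = x$samples),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a two-column time/value CSV as a raw signal
#'
#' The sampling rate is inferred from the median time step unless given.
#'
#' @param file CSV with columns `time_s`, `value`.
#' @param channel `"ECG"` or `"EDA"`.
#' @param fs Optional sampling rate override in Hz.
#' @return A `raw_signal`.
#' @export
read_signal_csv <- function(file, channel = c("ECG", "EDA"), fs = NULL) {
  channel <- match.arg(channel)
  d <- utils::read.csv(file)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("read_signal_csv: need columns time_s, value")
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  raw_signal(d$value, fs = fs, channel = channel)
}
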