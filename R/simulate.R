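# Synthetic cohort generator. Beat times come from an integral pulse
# frequency modulation (IPFM) model whose rate is modulated at the LF and HF
# rhythms (plus an optional very-low-frequency term and broadband rate
# noise); skin conductance is a slowly varying tonic curve plus a Poisson
# train of Bateman-kernel responses. Ground truth is returned alongside every
# recording so feature extraction can be validated against it.

#' Condition profile for the synthetic generator
#'
#' Bundles the generative parameters that define one task condition
#' (baseline, psychomotor vigilance, n-back, ship search). Cardiac
#' parameters drive the IPFM beat generator; electrodermal parameters drive
#' the tonic + phasic skin-conductance model.
#'
#' @param condition_label One of `"BL"`, `"PVT"`, `"NBACK"`, `"SS"`.
#' @param mean_hr Mean heart rate, beats/min; must lie in (30, 200).
#' @param lf_mod_amp,hf_mod_amp Dimensionless modulation depths of the
#'   heart-rate rhythm at `f_LF` and `f_HF`; non-negative, and their sum
#'   (with `vlf_mod_amp`) must stay below 1 so the rate stays positive.
#' @param f_LF,f_HF Modulation frequencies, Hz; constrained to the LF
#'   (0.045-0.15) and HF (0.15-0.4) bands.
#' @param vlf_mod_amp,f_VLF Optional very-low-frequency modulation (below
#'   the LF band) so normalized LF/HF indices leave room for VLF power.
#' @param mod_noise_depth Standard deviation of broadband (low-passed white)
#'   rate modulation; gives realistic trial-to-trial index spread.
#' @param tonic_level Tonic skin conductance level, microsiemens.
#' @param tonic_drift_slope Linear tonic drift, microsiemens/min.
#' @param tonic_osc_amp,tonic_osc_freq Slow tonic oscillation (freq must be
#'   below 0.02 Hz).
#' @param scr_rate Skin conductance response rate, events/min.
#' @param scr_amp_log_mean,scr_amp_log_sd Log-normal SCR amplitude
#'   parameters (log-microsiemens).
#' @param noise_sd_ecg,noise_sd_eda Additive white measurement noise (mV,
#'   microsiemens).
#' @return An object of class `condition_profile`.
#' @export
condition_profile <- function(condition_label,
                              mean_hr = 70,
                              lf_mod_amp = 0.08, hf_mod_amp = 0.06,
                              f_LF = 0.1, f_HF = 0.3,
                              vlf_mod_amp = 0.08, f_VLF = 0.03,
                              mod_noise_depth = 0.03,
                              tonic_level = 2, tonic_drift_slope = 0.02,
                              tonic_osc_amp = 0.1, tonic_osc_freq = 0.01,
                              scr_rate = 2.5,
                              scr_amp_log_mean = log(0.4),
                              scr_amp_log_sd = 0.5,
                              noise_sd_ecg = 0.05, noise_sd_eda = 0.01) {
  if (!condition_label %in% condition_levels())
    stop("condition_profile: unknown condition label '", condition_label, "'")
  if (mean_hr <= 30 || mean_hr >= 200)
    stop("condition_profile: mean_hr must lie in (30, 200)")
  if (lf_mod_amp < 0 || hf_mod_amp < 0 || vlf_mod_amp < 0)
    stop("condition_profile: modulation depths must be non-negative")
  if (lf_mod_amp + hf_mod_amp >= 1)
    stop("condition_profile: lf_mod_amp + hf_mod_amp must be < 1")
  if (f_LF < 0.045 || f_LF > 0.15)
    stop("condition_profile: f_LF must lie in [0.045, 0.15]")
  if (f_HF < 0.15 || f_HF > 0.4)
    stop("condition_profile: f_HF must lie in [0.15, 0.4]")
  if (scr_rate < 0) stop("condition_profile: scr_rate must be >= 0")
  if (tonic_osc_freq >= 0.02)
    stop("condition_profile: tonic_osc_freq must be < 0.02 Hz")
  structure(list(condition_label = condition_label, mean_hr = mean_hr,
                 lf_mod_amp = lf_mod_amp, hf_mod_amp = hf_mod_amp,
                 f_LF = f_LF, f_HF = f_HF,
                 vlf_mod_amp = vlf_mod_amp, f_VLF = f_VLF,
                 mod_noise_depth = mod_noise_depth,
                 tonic_level = tonic_level,
                 tonic_drift_slope = tonic_drift_slope,
                 tonic_osc_amp = tonic_osc_amp,
                 tonic_osc_freq = tonic_osc_freq,
                 scr_rate = scr_rate,
                 scr_amp_log_mean = scr_amp_log_mean,
                 scr_amp_log_sd = scr_amp_log_sd,
                 noise_sd_ecg = noise_sd_ecg,
                 noise_sd_eda = noise_sd_eda),
            class = "condition_profile")
}

#' Default condition profiles patterned on the study conditions
#'
#' Tonic levels and SCR rates follow the reported condition means (SCL 0.19,
#' 3.5, 4.6, 5.6 microsiemens; NS.SCRs 2.1, 3.1, 2.1, 2.5 per min for BL,
#' PVT, n-back, SS). Cardiac modulation depths are set so the normalized
#' LF/HF indices pattern as reported (n-back lowest LFn, PVT highest HFn),
#' with a VLF term filling the remainder of total power. SCR amplitudes are
#' larger for ship search and smaller for n-back, reproducing the reported
#' EDASymp/TVSymp ordering (SS highest, n-back lowest).
#'
#' @return Named list of four `condition_profile`s (`BL`, `PVT`, `NBACK`,
#'   `SS`).
#' @export
default_condition_profiles <- function() {
  # depths ~ sqrt(target power share) scaled to a total depth of ~0.25
  mk <- function(label, hr, lfn, hfn, tonic, rate, amp_mu) {
    sh <- c(lfn, hfn, max(0.05, 1 - lfn - hfn))
    a <- 0.25 * sqrt(sh) / sum(sqrt(sh))
    condition_profile(label, mean_hr = hr,
                      lf_mod_amp = a[1], hf_mod_amp = a[2],
                      vlf_mod_amp = a[3],
                      tonic_level = tonic, scr_rate = rate,
                      scr_amp_log_mean = log(amp_mu))
  }
  list(BL    = mk("BL",    65, 0.35, 0.21, 0.19, 2.1, 0.30),
       PVT   = mk("PVT",   70, 0.40, 0.26, 3.5,  3.1, 0.45),
       NBACK = mk("NBACK", 72, 0.24, 0.16, 4.6,  2.1, 0.25),
       SS    = mk("SS",    70, 0.38, 0.20, 5.6,  2.5, 0.60))
}

#' Simulate beat times by integral pulse frequency modulation
#'
#' The instantaneous beat rate (beats/s) is
#' `m(t) = (mean_hr/60) * (1 + a_lf sin(2 pi f_LF t + p1)
#'                           + a_hf sin(2 pi f_HF t + p2) + ...)`,
#' optionally including the VLF term and broadband rate noise. A beat is
#' emitted at every unit crossing of the integral of `m`; the deterministic
#' part of the integral is evaluated in closed form on a fine grid and beat
#' times are found by inverse interpolation of the strictly increasing
#' integral.
#'
#' @param profile A `condition_profile`.
#' @param duration Recording length, s (>= 240).
#' @param seed Integer seed; fixes the modulation phases and rate noise.
#' @param random_phase If `FALSE`, all modulation phases are zero.
#' @return List with `rr` (an [rr_series()]) and `truth` (list with
#'   `beat_times`, modulation depths used).
#' @export
generate_rr <- function(profile, duration, seed, random_phase = TRUE) {
  stopifnot(inherits(profile, "condition_profile"))
  if (duration < 240) stop("generate_rr: duration must be >= 240 s")
  a <- c(profile$lf_mod_amp, profile$hf_mod_amp, profile$vlf_mod_amp)
  f <- c(profile$f_LF, profile$f_HF, profile$f_VLF)
  base <- profile$mean_hr / 60
  dt <- 0.05
  tg <- seq(0, duration, by = dt)
  res <- withr::with_seed(seed, {
    ph <- if (random_phase) stats::runif(3, 0, 2 * pi) else rep(0, 3)
    noise <- if (profile$mod_noise_depth > 0) {
      z <- stats::rnorm(length(tg))
      z <- fft_lowpass(z, fs = 1 / dt, cutoff = 0.5)
      z <- z / stats::sd(z) * profile$mod_noise_depth
      pmax(pmin(z, 3.5 * profile$mod_noise_depth),
           -3.5 * profile$mod_noise_depth)
    } else numeric(length(tg))
    list(ph = ph, noise = noise)
  })
  ph <- res$ph; noise <- res$noise
  m <- base * (1 +
                 a[1] * sin(2 * pi * f[1] * tg + ph[1]) +
                 a[2] * sin(2 * pi * f[2] * tg + ph[2]) +
                 a[3] * sin(2 * pi * f[3] * tg + ph[3]) +
                 noise)
  if (any(m <= 0))
    stop("generate_rr: modulation drives the beat rate to zero or below")
  # closed-form integral of the sinusoidal part + trapezoid for the noise
  M_det <- base * (tg -
    a[1] / (2 * pi * f[1]) * (cos(2 * pi * f[1] * tg + ph[1]) - cos(ph[1])) -
    a[2] / (2 * pi * f[2]) * (cos(2 * pi * f[2] * tg + ph[2]) - cos(ph[2])) -
    a[3] / (2 * pi * f[3]) * (cos(2 * pi * f[3] * tg + ph[3]) - cos(ph[3])))
  M <- M_det + base * as.numeric(pracma::cumtrapz(tg, noise))
  n_beats <- floor(M[length(M)])
  beat_times <- stats::approx(M, tg, xout = seq(0, n_beats))$y
  list(rr = rr_series(beat_times),
       truth = list(beat_times = beat_times,
                    mod_amps = stats::setNames(a, c("lf", "hf", "vlf")),
                    phases = ph))
}

# Stereotyped biphasic QRS-like template, ~80 ms wide, 1 mV peak at u = 0.
qrs_template <- function(u) {
  1.0  * exp(-u^2 / (2 * 0.010^2)) -
  0.25 * exp(-(u - 0.028)^2 / (2 * 0.014^2)) -
  0.08 * exp(-(u + 0.028)^2 / (2 * 0.012^2))
}

#' Synthesize an ECG waveform from beat times
#'
#' Places a stereotyped biphasic QRS template (about 80 ms wide, 1 mV peak)
#' at every beat time and adds slow baseline wander and white noise. The
#' morphology is deliberately minimal: it exists so the R-peak detector has
#' realistic work to do, not to mimic full PQRST shape.
#'
#' @param rr An `rr_series` (simulated or detected).
#' @param fs Sampling rate, Hz (>= 128).
#' @param seed Integer seed for wander phase and noise.
#' @param noise_sd White noise SD, mV.
#' @param wander_amp,wander_freq Baseline wander amplitude (mV) and
#'   frequency (Hz, <= 0.3).
#' @param duration Output length, s; defaults to the last beat time rounded
#'   up to a whole second.
#' @return A `raw_signal` (channel ECG).
#' @export
synthesize_ecg <- function(rr, fs = 256, seed = 1, noise_sd = 0.05,
                           wander_amp = 0.1, wander_freq = 0.25,
                           duration = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 128) stop("synthesize_ecg: fs must be >= 128 Hz")
  if (wander_freq > 0.3) stop("synthesize_ecg: wander_freq must be <= 0.3 Hz")
  if (is.null(duration)) duration <- ceiling(max(rr$beat_times))
  n <- round(duration * fs)
  x <- numeric(n)
  half <- round(0.1 * fs)
  for (b in rr$beat_times) {
    i0 <- max(1L, floor(b * fs) - half)
    i1 <- min(n, floor(b * fs) + half)
    if (i1 < i0) next
    idx <- i0:i1
    x[idx] <- x[idx] + qrs_template((idx - 1) / fs - b)
  }
  x <- x + withr::with_seed(seed, {
    ph <- stats::runif(1, 0, 2 * pi)
    wander_amp * sin(2 * pi * wander_freq * (seq_len(n) - 1) / fs + ph) +
      stats::rnorm(n, sd = noise_sd)
  })
  raw_signal(x, fs = fs, channel = "ECG")
}

#' Peak-normalized Bateman kernel
#'
#' Difference of exponentials `exp(-t/t_decay) - exp(-t/t_rise)`, scaled to
#' unit peak, modelling the rise and recovery of one skin conductance
#' response.
#'
#' @param fs Sampling rate, Hz.
#' @param t_rise,t_decay Time constants, s.
#' @param length_s Kernel support, s.
#' @return Numeric kernel sampled at `fs`.
#' @export
bateman_kernel <- function(fs = 8, t_rise = 0.75, t_decay = 10,
                           length_s = 40) {
  t <- seq(0, length_s, by = 1 / fs)
  k <- exp(-t / t_decay) - exp(-t / t_rise)
  k / max(k)
}

#' Synthesize a skin conductance recording
#'
#' Signal = tonic (level + linear drift + slow sinusoid) + sum of
#' Bateman-kernel responses at Poisson event times with log-normal
#' amplitudes + white noise. Event times/amplitudes can be supplied
#' explicitly, overriding the Poisson draw (useful for controlled recovery
#' experiments).
#'
#' @param profile A `condition_profile`.
#' @param duration Recording length, s (>= 120).
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param event_times,event_amps Optional explicit SCR events (s,
#'   microsiemens); both or neither.
#' @return List with `eda` (a `raw_signal`) and `truth` (list with
#'   `scr_event_times`, `scr_event_amps`, `tonic_curve`).
#' @export
synthesize_eda <- function(profile, duration = 120, fs = 8, seed = 1,
                           event_times = NULL, event_amps = NULL) {
  stopifnot(inherits(profile, "condition_profile"))
  if (duration < 120) stop("synthesize_eda: duration must be >= 120 s")
  if (is.null(event_times) != is.null(event_amps))
    stop("synthesize_eda: supply event_times and event_amps together")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  ev <- withr::with_seed(seed, {
    ph <- stats::runif(1, 0, 2 * pi)
    if (is.null(event_times)) {
      k <- stats::rpois(1, profile$scr_rate * duration / 60)
      event_times <- sort(stats::runif(k, 0, duration))
      event_amps <- stats::rlnorm(k, profile$scr_amp_log_mean,
                                  profile$scr_amp_log_sd)
    }
    noise <- if (profile$noise_sd_eda > 0)
      stats::rnorm(n, sd = profile$noise_sd_eda) else numeric(n)
    list(times = event_times, amps = event_amps, ph = ph, noise = noise)
  })
  tonic <- profile$tonic_level +
    profile$tonic_drift_slope * t / 60 +
    profile$tonic_osc_amp * sin(2 * pi * profile$tonic_osc_freq * t + ev$ph)
  driver <- numeric(n)
  if (length(ev$times) > 0) {
    idx <- pmin(n, pmax(1L, round(ev$times * fs) + 1L))
    for (j in seq_along(idx)) driver[idx[j]] <- driver[idx[j]] + ev$amps[j]
  }
  kern <- bateman_kernel(fs = fs)
  phasic <- stats::convolve(driver, rev(kern), type = "open")[seq_len(n)]
  raw <- raw_signal(tonic + phasic + ev$noise, fs = fs, channel = "EDA")
  list(eda = raw,
       truth = list(scr_event_times = ev$times, scr_event_amps = ev$amps,
                    tonic_curve = tonic))
}

# Deterministic per-recording seed derived from the cohort seed; kept below
# 2^31 - 1.
recording_seed <- function(seed, subject, trial, cond_idx, channel = 0L) {
  as.integer((as.double(seed) * 1000003 + subject * 98947 +
                trial * 1013 + cond_idx * 31 + channel) %% 2147483629)
}

# Apply per-subject offsets and the trial-level fatigue attenuation to a
# condition profile. lambda = 1 keeps full separation from baseline;
# lambda < 1 shrinks condition parameters toward the baseline profile.
effective_profile <- function(profile, baseline, eff, lambda = 1) {
  p <- profile
  blend <- function(field) baseline[[field]] +
    lambda * (profile[[field]] - baseline[[field]])
  if (lambda < 1 && profile$condition_label != "BL")
    for (field in c("mean_hr", "lf_mod_amp", "hf_mod_amp", "vlf_mod_amp",
                    "tonic_level", "scr_rate", "scr_amp_log_mean"))
      p[[field]] <- blend(field)
  p$mean_hr <- min(199, max(31, p$mean_hr + eff$hr_offset))
  p$lf_mod_amp <- p$lf_mod_amp * eff$lf_fac
  p$hf_mod_amp <- p$hf_mod_amp * eff$hf_fac
  p$vlf_mod_amp <- p$vlf_mod_amp * eff$vlf_fac
  tot <- p$lf_mod_amp + p$hf_mod_amp + p$vlf_mod_amp + p$mod_noise_depth
  if (tot >= 0.9) {  # keep the rate safely positive
    sc <- 0.9 / tot
    p$lf_mod_amp <- p$lf_mod_amp * sc
    p$hf_mod_amp <- p$hf_mod_amp * sc
    p$vlf_mod_amp <- p$vlf_mod_amp * sc
  }
  p$tonic_level <- p$tonic_level + eff$tonic_offset
  p$scr_rate <- max(0, p$scr_rate + eff$rate_offset)
  p$scr_amp_log_mean <- p$scr_amp_log_mean + eff$amp_log_offset
  p
}

# Draw per-subject random effects once.
draw_subject_effects <- function(n_subjects, seed,
                                 sd_hr = 6, sd_tonic = 1.5, sd_rate = 0.7,
                                 sd_logdepth = 0.2, sd_amplog = 0.2) {
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(s)
      list(subject_id = s,
           hr_offset = stats::rnorm(1, sd = sd_hr),
           tonic_offset = stats::rnorm(1, sd = sd_tonic),
           rate_offset = stats::rnorm(1, sd = sd_rate),
           lf_fac = stats::rlnorm(1, 0, sd_logdepth),
           hf_fac = stats::rlnorm(1, 0, sd_logdepth),
           vlf_fac = stats::rlnorm(1, 0, sd_logdepth),
           amp_log_offset = stats::rnorm(1, sd = sd_amplog)))
  })
}

# Simulate one labelled recording (both channels) with its truth records.
simulate_recording <- function(profile, baseline, eff, subject, trial,
                               cond_idx, seed, lambda = 1,
                               ecg_duration = 244, eda_duration = 124,
                               ecg_fs = 256, eda_fs = 8) {
  p <- effective_profile(profile, baseline, eff, lambda)
  s_rr <- recording_seed(seed, subject, trial, cond_idx, 0L)
  s_ecg <- recording_seed(seed, subject, trial, cond_idx, 1L)
  s_eda <- recording_seed(seed, subject, trial, cond_idx, 2L)
  rr <- generate_rr(p, duration = ecg_duration, seed = s_rr)
  ecg <- synthesize_ecg(rr$rr, fs = ecg_fs, seed = s_ecg,
                        noise_sd = p$noise_sd_ecg,
                        duration = ecg_duration)
  eda <- synthesize_eda(p, duration = eda_duration, fs = eda_fs,
                        seed = s_eda)
  list(subject_id = subject, trial = trial,
       condition = p$condition_label,
       ecg = ecg, eda = eda$eda,
       truth = c(rr$truth, eda$truth))
}

#' Generate a labelled synthetic cohort
#'
#' For every subject x trial x condition, simulates one ECG and one EDA
#' recording. Per-subject additive/multiplicative random effects (drawn once
#' per subject) provide the between-subject variance leave-one-subject-out
#' evaluation needs; an optional per-trial "fatigue drift" multiplier
#' shrinks condition profiles toward baseline at later trials, emulating
#' attenuated autonomic separation under prolonged wakefulness.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_trials Number of repeated trials per subject.
#' @param profiles Named list of four `condition_profile`s covering BL, PVT,
#'   NBACK, SS.
#' @param seed Integer cohort seed; the same seed reproduces the cohort
#'   bit-for-bit.
#' @param fatigue Numeric vector of separation multipliers per trial (values
#'   in [0, 1]; recycled/truncated to `n_trials`). 1 = full separation.
#' @param subject_sd Optional named list overriding the between-subject
#'   effect SDs (`sd_hr`, `sd_tonic`, `sd_rate`, `sd_logdepth`,
#'   `sd_amplog`).
#' @param ecg_duration,eda_duration,ecg_fs,eda_fs Recording lengths (s) and
#'   rates (Hz).
#' @return An object of class `ans_cohort`: list with `recordings` (list of
#'   per-recording lists holding `raw_signal`s and truth sidecars),
#'   `manifest` (data.frame), and the generation parameters.
#' @export
generate_cohort <- function(n_subjects = 16, n_trials = 12,
                            profiles = default_condition_profiles(),
                            seed = 1, fatigue = NULL, subject_sd = list(),
                            ecg_duration = 244, eda_duration = 124,
                            ecg_fs = 256, eda_fs = 8) {
  if (n_subjects < 2) stop("generate_cohort: need n_subjects >= 2")
  if (!all(condition_levels() %in%
             vapply(profiles, `[[`, "", "condition_label")))
    stop("generate_cohort: profiles must cover all four conditions")
  ids <- vapply(profiles, `[[`, "", "condition_label")
  if (anyDuplicated(ids)) stop("generate_cohort: duplicate condition profile")
  names(profiles) <- ids
  if (is.null(fatigue)) fatigue <- rep(1, n_trials)
  fatigue <- rep_len(fatigue, n_trials)
  eff <- do.call(draw_subject_effects,
                 c(list(n_subjects = n_subjects, seed = seed), subject_sd))
  if (anyDuplicated(vapply(eff, `[[`, 0, "subject_id")))
    stop("generate_cohort: duplicate subject_id")
  recs <- list()
  man <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) for (tr in seq_len(n_trials))
    for (ci in seq_along(condition_levels())) {
      cond <- condition_levels()[ci]
      k <- k + 1L
      recs[[k]] <- simulate_recording(profiles[[cond]], profiles[["BL"]],
                                      eff[[s]], s, tr, ci, seed,
                                      lambda = fatigue[tr],
                                      ecg_duration = ecg_duration,
                                      eda_duration = eda_duration,
                                      ecg_fs = ecg_fs, eda_fs = eda_fs)
      man[[k]] <- data.frame(subject_id = s, trial = tr, condition = cond,
                             ecg_fs = ecg_fs, eda_fs = eda_fs,
                             seed = recording_seed(seed, s, tr, ci, 0L))
    }
  structure(list(recordings = recs,
                 manifest = do.call(rbind, man),
                 n_subjects = n_subjects, n_trials = n_trials,
                 seed = seed, fatigue = fatigue, profiles = profiles),
            class = "ans_cohort")
}

#' @export
print.ans_cohort <- function(x, ...) {
  cat(sprintf(
    "<ans_cohort> %d subjects x %d trials x 4 conditions = %d recordings (seed %d)\n",
    x$n_subjects, x$n_trials, length(x$recordings), x$seed))
  invisible(x)
}

#' Write a cohort to a directory of CSV recordings
#'
#' One two-column CSV per channel per recording, a manifest table, and a
#' JSON truth sidecar per recording (event times/amplitudes, beat times).
#'
#' @param cohort An `ans_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (invisibly), with file columns added.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ans_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$ecg_file <- man$eda_file <- man$truth_file <- NA_character_
  for (i in seq_along(cohort$recordings)) {
    r <- cohort$recordings[[i]]
    stem <- sprintf("s%02d_t%02d_%s", r$subject_id, r$trial, r$condition)
    man$ecg_file[i] <- paste0(stem, "_ecg.csv")
    man$eda_file[i] <- paste0(stem, "_eda.csv")
    man$truth_file[i] <- paste0(stem, "_truth.json")
    write_signal_csv(r$ecg, file.path(dir, man$ecg_file[i]))
    write_signal_csv(r$eda, file.path(dir, man$eda_file[i]))
    jsonlite::write_json(
      list(beat_times = r$truth$beat_times,
           scr_event_times = r$truth$scr_event_times,
           scr_event_amps = r$truth$scr_event_amps,
           mod_amps = as.list(r$truth$mod_amps)),
      file.path(dir, man$truth_file[i]), digits = NA)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
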