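# Independent oracles and fixture builders used across the test files.

# Dense numerical IPFM solver: integrates the modulated rate on a 1 kHz
# grid (plain cumulative sum, no closed form) and finds unit crossings.
# Independent of the package's closed-form + inverse-interpolation path.
oracle_ipfm <- function(mean_hr, amps, freqs, phases, duration,
                        dt = 1e-3) {
  tg <- seq(0, duration, by = dt)
  m <- rep(mean_hr / 60, length(tg))
  for (j in seq_along(amps))
    m <- m + (mean_hr / 60) * amps[j] * sin(2 * pi * freqs[j] * tg +
                                              phases[j])
  M <- dt * (cumsum(m) - m[1])
  stats::approx(M, tg, xout = 0:floor(max(M)))$y
}

# Gaussian labelled feature table: class ci has mean `sep` on feature ci
# (features beyond 4 are pure noise). Used wherever classification logic,
# not signal processing, is under test.
make_feature_table <- function(n_subjects, sep = 3, trial = 1, seed = 1,
                               informative = 1:4) {
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) for (ci in 1:4) {
      mu <- rep(0, 8)
      if (length(informative) == 1) mu[informative] <- sep * ci
      else mu[informative[ci]] <- sep
      x <- stats::rnorm(8, mu, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, trial = trial,
        condition = condition_levels()[ci],
        t(stats::setNames(x, feature_names())))
    }
    do.call(rbind, rows)
  })
}

# Strongly separated condition profiles with tight subject effects: every
# channel pushes the four conditions far apart (distinct tonic levels, SCR
# rates and amplitudes, heart rates and LF/HF modulation signatures), so
# extraction + LOSO should classify perfectly.
separated_profiles <- function() {
  list(BL = condition_profile("BL", mean_hr = 60, tonic_level = 1,
                              scr_rate = 0.5, scr_amp_log_mean = log(0.3),
                              lf_mod_amp = 0.18, hf_mod_amp = 0.02,
                              vlf_mod_amp = 0.05, mod_noise_depth = 0.01),
       PVT = condition_profile("PVT", mean_hr = 75, tonic_level = 7,
                               scr_rate = 3, scr_amp_log_mean = log(0.5),
                               lf_mod_amp = 0.02, hf_mod_amp = 0.18,
                               vlf_mod_amp = 0.05, mod_noise_depth = 0.01),
       NBACK = condition_profile("NBACK", mean_hr = 95, tonic_level = 14,
                                 scr_rate = 6, scr_amp_log_mean = log(0.3),
                                 lf_mod_amp = 0.1, hf_mod_amp = 0.1,
                                 vlf_mod_amp = 0.05,
                                 mod_noise_depth = 0.01),
       SS = condition_profile("SS", mean_hr = 120, tonic_level = 22,
                              scr_rate = 9, scr_amp_log_mean = log(0.9),
                              lf_mod_amp = 0.05, hf_mod_amp = 0.05,
                              vlf_mod_amp = 0.18, mod_noise_depth = 0.01))
}

tight_subject_sd <- function() {
  list(sd_hr = 0.5, sd_tonic = 0.1, sd_rate = 0.2, sd_logdepth = 0.02,
       sd_amplog = 0.02)
}

# Quiet profile for controlled EDA constructions.
quiet_eda_profile <- function(tonic = 2) {
  condition_profile("BL", tonic_level = tonic, tonic_drift_slope = 0,
                    tonic_osc_amp = 0, noise_sd_eda = 0, scr_rate = 0)
}
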