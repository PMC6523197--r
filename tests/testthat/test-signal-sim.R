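# Synthetic generator: IPFM beat model, ECG/EDA waveform synthesis, cohort
# assembly, and the seed/reproducibility contracts.

test_that("unmodulated IPFM yields constant intervals, reproducibly", {
  p <- condition_profile("BL", mean_hr = 60, lf_mod_amp = 0,
                         hf_mod_amp = 0, vlf_mod_amp = 0,
                         mod_noise_depth = 0)
  g <- generate_rr(p, 240, seed = 1)
  expect_equal(unname(range(g$rr$rr_ms)), c(1000, 1000), tolerance = 1e-6)
  g2 <- generate_rr(p, 240, seed = 1)
  expect_identical(g$truth$beat_times, g2$truth$beat_times)
  g3 <- condition_profile("BL", mean_hr = 60) |>
    generate_rr(240, seed = 1)
  g4 <- generate_rr(condition_profile("BL", mean_hr = 60), 240, seed = 2)
  expect_false(identical(g3$truth$beat_times, g4$truth$beat_times))
})

test_that("IPFM beat times and LF/HF power ratio match the dense solver", {
  p <- condition_profile("BL", mean_hr = 70, lf_mod_amp = 0.1,
                         hf_mod_amp = 0.05, vlf_mod_amp = 0,
                         mod_noise_depth = 0)
  ratios <- oratios <- numeric(5)
  for (sd in 1:5) {
    g <- generate_rr(p, 240, seed = sd)
    ob <- oracle_ipfm(70, c(0.1, 0.05), c(0.1, 0.3),
                      g$truth$phases[1:2], 240)
    n <- min(length(ob), length(g$truth$beat_times))
    expect_lt(max(abs(g$truth$beat_times[1:n] - ob[1:n])), 1e-3)
    hi <- hrv_band_indices(averaged_spectrum(uniform_rr(
      g$truth$beat_times)))
    oh <- hrv_band_indices(averaged_spectrum(uniform_rr(ob)))
    ratios[sd] <- hi$HRVLF / hi$HRVHF
    oratios[sd] <- oh$HRVLF / oh$HRVHF
  }
  expect_lt(abs(mean(ratios) / mean(oratios) - 1), 0.25)
})

test_that("LF spectral power scales with modulation depth squared", {
  depths <- c(0.02, 0.05, 0.08, 0.12)
  lf_power <- vapply(depths, function(a) {
    p <- condition_profile("BL", mean_hr = 70, lf_mod_amp = a,
                           hf_mod_amp = 0, vlf_mod_amp = 0,
                           mod_noise_depth = 0)
    mean(vapply(1:3, function(sd) {
      g <- generate_rr(p, 240, seed = sd)
      hrv_band_indices(averaged_spectrum(uniform_rr(
        g$truth$beat_times)))$HRVLF
    }, 0))
  }, 0)
  expect_identical(order(lf_power), seq_along(depths))  # rank corr = 1
  # quadratic growth: doubling depth ~ quadruples power
  expect_equal(lf_power[3] / lf_power[1], (0.08 / 0.02)^2,
               tolerance = 0.35)
})

test_that("modulation driving the rate non-positive is rejected", {
  expect_error(condition_profile("BL", lf_mod_amp = 0.6, hf_mod_amp = 0.5),
               "< 1")
  p <- condition_profile("BL", lf_mod_amp = 0.5, hf_mod_amp = 0.3,
                         vlf_mod_amp = 0.35, mod_noise_depth = 0)
  expect_error(generate_rr(p, 240, seed = 1), "zero or below")
})

test_that("ECG synthesis places peaks at beat times with the right length", {
  p <- condition_profile("BL", mean_hr = 65)
  g <- generate_rr(p, 240, seed = 3)
  ecg <- synthesize_ecg(g$rr, fs = 256, seed = 1, noise_sd = 0,
                        wander_amp = 0, duration = 240)
  expect_length(ecg$samples, 61440)  # 240 s x 256 Hz
  x <- ecg$samples
  interior <- g$truth$beat_times[g$truth$beat_times > 0.2 &
                                   g$truth$beat_times < 239.8]
  for (b in interior[seq(1, length(interior), by = 25)]) {
    i <- round(b * 256) + 1
    win <- x[(i - 26):(i + 26)]
    expect_lte(abs(which.max(win) - 27), 1)  # peak within +/- 1 sample
  }
})

test_that("beats are recovered from noisy synthetic ECG", {
  p <- condition_profile("BL", mean_hr = 70)
  g <- generate_rr(p, 244, seed = 11)
  ecg <- synthesize_ecg(g$rr, fs = 256, seed = 4, noise_sd = 0.05,
                        duration = 244)
  det <- detect_r_peaks(ecg)
  truth <- g$truth$beat_times
  hits <- vapply(truth, function(b) any(abs(det - b) <= 0.010), FALSE)
  matched <- vapply(det, function(b) any(abs(truth - b) <= 0.010), FALSE)
  expect_gte(mean(hits), 0.99)     # sensitivity
  expect_gte(mean(matched), 0.99)  # precision
})

test_that("EDA synthesis covers constant, event and condition contrasts", {
  pq <- quiet_eda_profile(tonic = 3)
  e0 <- synthesize_eda(pq, 120, seed = 1)
  expect_equal(unname(range(e0$eda$samples)), c(3, 3))
  # condition-mean contrast: SS-like vs BL-like tonic levels
  prof <- default_condition_profiles()
  dmeans <- vapply(1:6, function(sd)
    mean(synthesize_eda(prof$SS, 120, seed = sd)$eda$samples) -
      mean(synthesize_eda(prof$BL, 120, seed = sd + 100)$eda$samples),
    0)
  expect_equal(mean(dmeans), 5.4, tolerance = 0.5)
})

test_that("SCR event count is Poisson-consistent with the configured rate", {
  p <- condition_profile("BL", scr_rate = 3)
  counts <- vapply(1:100, function(sd)
    length(synthesize_eda(p, 120, seed = sd)$truth$scr_event_times), 0)
  expected <- 3 * 2                      # rate x minutes
  se <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("cohort assembly yields balanced labelled recordings", {
  ch <- generate_cohort(n_subjects = 2, n_trials = 3, seed = 5,
                        ecg_duration = 244, eda_duration = 124)
  expect_s3_class(ch, "ans_cohort")
  expect_length(ch$recordings, 24)
  expect_equal(unname(table(ch$manifest$condition)), rep(6L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(ch$manifest$subject_id)), rep(12L, 2),
               ignore_attr = TRUE)
  # seed contract: different cohort seeds move the SCR event times
  ch2 <- generate_cohort(n_subjects = 2, n_trials = 1, seed = 6)
  ch1 <- generate_cohort(n_subjects = 2, n_trials = 1, seed = 5)
  expect_false(identical(ch1$recordings[[1]]$truth$scr_event_times,
                         ch2$recordings[[1]]$truth$scr_event_times))
  # same seed: bit-for-bit identical
  ch1b <- generate_cohort(n_subjects = 2, n_trials = 1, seed = 5)
  expect_identical(ch1$recordings[[1]]$ecg$samples,
                   ch1b$recordings[[1]]$ecg$samples)
})

test_that("cohort writing produces per-recording files and a manifest", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(n_subjects = 2, n_trials = 1, seed = 9)
  man <- write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 8)
  expect_true(all(file.exists(file.path(dir, man$ecg_file))))
  sig <- read_signal_csv(file.path(dir, man$eda_file[1]), channel = "EDA")
  expect_equal(sig$fs, 8, tolerance = 1e-6)
  expect_equal(sig$samples, ch$recordings[[1]]$eda$samples,
               tolerance = 1e-6)
})
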