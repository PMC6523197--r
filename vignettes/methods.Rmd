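---
title: "Methods: autonomic indices and task classification in ansid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomic indices and task classification in ansid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Overview

`ansid` implements a complete task-identification analysis for
psychophysiology: eight autonomic indices are extracted from ECG (heart
rate variability, HRV) and skin conductance (electrodermal activity, EDA)
recordings, and seven classifiers are evaluated under
leave-one-subject-out (LOSO) cross-validation to identify which of four
conditions — rest baseline (BL), psychomotor vigilance (PVT), auditory
working memory (n-back, NBACK), and visual ship search (SS) — a subject was
performing. Because the analysis must be testable without human
recordings, the package includes a first-class synthetic-cohort generator
with known ground truth; every extraction stage is validated against that
truth.

The eight indices, in the canonical column order used everywhere, are:

| Index | Units | Source | Meaning |
|---|---|---|---|
| SCL | µS | EDA tonic | mean skin conductance level |
| NS_SCRs | /min | EDA phasic | non-specific SCRs above 0.05 µS |
| EDASymp | µS² | EDA spectrum | power in 0.045–0.25 Hz |
| TVSymp | n.u. | EDA time-frequency | mean in-band instantaneous amplitude |
| HRVLF | ms² | RR spectrum | power in 0.045–0.15 Hz |
| HRVLFn | n.u. | RR spectrum | HRVLF / total power |
| HRVHF | ms² | RR spectrum | power in 0.15–0.4 Hz |
| HRVHFn | n.u. | RR spectrum | HRVHF / total power |

# HRV extraction

Each ECG segment (the first 240 s of a recording) is band-pass filtered at
0.05–40 Hz (2nd-order zero-phase Butterworth). R peaks are found with a
derivative–square–moving-window-integration detector: the rectified
derivative energy is smoothed over 150 ms, thresholded at one quarter of
its 98th percentile, and each supra-threshold onset is refined to the
local maximum of the filtered ECG within ±100 ms, with a 250 ms refractory
period. A recording yielding fewer than 60 beats raises a signal-quality
error. On noiseless synthetic ECG the detector recovers every beat to
within one sample; with 0.05 mV white noise, sensitivity and precision
stay above 99% (both are tested).

RR intervals outside 250–3000 ms are discarded before interpolation; this
automatic range rule stands in for the manual beat inspection an operator
would do on real data. The cleaned tachogram — each interval timestamped
at its closing beat — is cubic-spline resampled to an even 4 Hz grid. The
spectrum is an averaged modified periodogram: 256-sample segments with 50%
overlap, per-segment mean removal, a Blackman window, and window-power
normalization so the integrated density matches the series variance
(Parseval; tested to 10% on white noise). With a 240 s segment this yields
exactly 6 averaged windows. Band powers are trapezoid-integrated with
linear interpolation at the exact band edges.

Two choices deserve comment. First, the overlap fraction for the HRV
periodogram is set to 50% to match the EDA spectral setting. Second,
normalized indices divide by power in a 0.003–0.4 Hz *total* band rather
than by LF+HF: reported normalized values in this kind of study sum to
well below 1, which implies the normalization includes a very-low-frequency
(VLF) contribution. Both are configurable through
`averaged_spectrum()` and `spectral_bands()`.

# EDA extraction

EDA is analyzed at 8 Hz (recordings at other rates are linearly
resampled; the channel is slow, so interpolation is benign) over the first
120 s.

**Tonic/phasic decomposition.** The signal is fit by sparsity-penalized,
non-negativity-constrained least squares to a two-part dictionary:
overlapping tent (ramp) atoms with 30 s knot spacing for the tonic level
(unpenalized, unconstrained — their bandwidth is well below 0.05 Hz, so
the tonic component cannot absorb phasic transients), and one
peak-normalized Bateman kernel
$h(t) = e^{-t/\tau_d} - e^{-t/\tau_r}$ (rise $\tau_r$ = 0.75 s, decay
$\tau_d$ = 10 s, 40 s support) per sample shift for the phasic driver
(non-negative, L1-penalized). The penalized fit is solved by coordinate
descent (glmnet); the active set is then refit *without* penalty — the
tonic subspace is projected out by QR and the driver re-estimated by
non-negative least squares — which removes the L1 shrinkage bias so event
amplitudes are unbiased. The default penalty (`lambda = 5e-4` on the µS
scale) was chosen so that noiseless synthetic input is reproduced with
residual power below 1% of signal variance while sub-threshold noise
activations stay sparse; it sits two orders of magnitude above the
correlation noise floor of the default 0.01 µS measurement noise.

One SCR event is one contiguous cluster of positive driver samples;
activations separated by less than 1 s are merged, since responses closer
than the kernel rise time are not separable. The event amplitude is the
peak of that cluster's kernel reconstruction — measured on the
reconstructed phasic component, not the raw signal, because raw maxima
conflate tonic drift. SCL is the mean of the tonic component; NS_SCRs
counts events whose amplitude exceeds 0.05 µS, per minute. On clean input
the recovery is exact (count, timing to the sample, amplitude), which the
acceptance tests exercise at 0, 3 and 6 planted events.

**EDASymp** is the Welch band power over 0.045–0.25 Hz using 128-sample
Blackman segments with 50% overlap — the same estimator as the HRV
spectrum at EDA scale.

**TVSymp** uses a complex demodulation bank: the mean-removed,
unit-variance-normalized signal is demodulated at center frequencies
$k \cdot 0.08$ Hz, low-pass filtered at 0.04 Hz by a zero-phase
raised-cosine FFT mask, and remodulated. Components whose bands overlap
0.08–0.24 Hz (the first three) are summed, and TVSymp is the time average
of the modulus of that sum's analytic signal. Normalizing the *input*
signal (rather than the in-band sum) makes TVSymp the in-band amplitude
fraction of total signal variability: a pure in-band sinusoid gives
$\sqrt 2 \approx 1.414$, broadband physiological input gives the familiar
0.3–0.5 range, and a constant signal gives 0 by definition. The bank is a
fixed-band first stage; instantaneous-frequency refinement of the centers
is deliberately omitted because components are selected by band, not
tracked. Its band partition is exact by construction, so band-limited
inputs reconstruct to better than 5% of variance (tested).

# The synthetic cohort

No public recordings accompany this analysis, so the generator *is* the
study-condition definition.

**Cardiac side.** Beat times follow integral pulse frequency modulation
(IPFM): a beat fires at each unit crossing of the integral of
$m(t) = \frac{\mathrm{HR}}{60}\,(1 + a_{LF}\sin 2\pi f_{LF} t
+ a_{HF}\sin 2\pi f_{HF} t + a_{VLF}\sin 2\pi f_{VLF} t + \eta(t))$,
with $f_{LF} = 0.1$, $f_{HF} = 0.3$, $f_{VLF} = 0.03$ Hz. The
deterministic integral is evaluated in closed form on a 50 ms grid and
inverted by interpolation; beat times agree with a 1 kHz brute-force
integration to < 1 ms. The VLF term exists so that normalized LF/HF
indices leave headroom for VLF power, as real tachograms do; $\eta$ is
broadband low-passed white modulation (depth 0.03 by default) giving
realistic within-condition index spread. Modulation that would drive the
rate non-positive is rejected. A minimal biphasic QRS template (~80 ms, 1
mV), 0.25 Hz baseline wander and white noise make the ECG waveform; the
point is to give the detector honest work, not to mimic PQRST morphology.

**Electrodermal side.** Tonic level + linear drift + a < 0.02 Hz
sinusoid, plus a Poisson train (rate = condition SCR rate) of
Bateman-kernel responses with log-normal amplitudes, plus white noise.
Event times and amplitudes can be supplied explicitly for controlled
recovery experiments.

**Condition profiles.** Defaults are patterned on the reported condition
summary: tonic levels 0.19 / 3.5 / 4.6 / 5.6 µS and SCR rates 2.1 / 3.1 /
2.1 / 2.5 per minute for BL / PVT / NBACK / SS; modulation depths are
proportional to the square roots of the target normalized LF / HF / VLF
power shares (scaled to a total depth of 0.25), so n-back has the lowest
LF fraction and PVT the highest HF fraction; SS has the largest and
n-back the smallest SCR amplitudes, reproducing the reported EDASymp /
TVSymp ordering. Per-subject random effects (heart-rate offset SD 6
beats/min, tonic offset SD 1.5 µS, SCR-rate offset SD 0.7/min, log-normal
depth factors SD 0.2) are drawn once per subject, giving LOSO its
between-subject generalization problem. A per-trial "fatigue drift"
multiplier shrinks condition profiles toward baseline; the default run
attenuates to 0.45 at trials 10–11 with recovery to 0.75 at trial 12,
emulating the weakened autonomic separation seen late in a 24-h
wakefulness protocol.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: PQRST morphology and ectopy, respiration and
its coupling to HF power, motion artifacts in either channel, circadian
structure beyond the scalar attenuation knob, and realistic correlations
*between* indices within a subject. Synthetic conditions are cleaner and
more symmetric than human data; classification accuracy on the default
cohort (~80–90% for the best models) is accordingly higher than the
60–66% regime reported for human subjects, and no test in this package
treats the published human accuracies or index magnitudes as
reproduction targets. In the same spirit, reported LF power in that
study (~7–11 "ms²") is far below typical physiological values,
suggesting an unstated transform; the package reports honest ms² and
makes no attempt to match those magnitudes.

# Classification

All seven families — 1-NN (Euclidean), linear SVM (C = 1), Gaussian SVM
(C = 1, γ = 2.6, kernel $e^{-\gamma\|x - x'\|^2}$, one-vs-one majority
vote), CART, LDA, QDA (uniform priors), and Mahalanobis-distance QDA
(class-specific covariance, ridge-regularized when near-singular) —
operate on features standardized by *training-fold* statistics only;
γ = 2.6 is only meaningful on a standardized scale, which motivates
per-fold z-scoring. LOSO uses one fold per subject; a fold whose training
half lacks a class is an error, not a silent skip. The exhaustive search
evaluates all $2^8 - 1 = 255$ subsets per classifier, ranks by accuracy
with ties broken toward fewer features and then canonical name order, and
re-runs the winner to confirm its accuracy. Temporal generalization
trains once on all trial-1 samples and applies the fixed model to each
later trial.

Two behaviors worth knowing: the permutation-null LOSO accuracy is
$(n_c - 1)/(N - 1)$, slightly below 25%, because labels are permuted
without replacement; and γ = 2.6 is so local in an 8-dimensional
standardized space that the Gaussian SVM approaches a majority vote on
diffuse data — visible in the subset-search report, where it trails the
other kernels, much as it does in the published human-subject ranking.

# Statistics

Per index: a one-sample Kolmogorov–Smirnov screen on z-scored values
(implemented exactly as stated for the original analysis; since the
parameters are estimated, this is the anti-conservative Lilliefors
situation and the package warns accordingly — in calibration it is in
fact conservative, rejecting well under 5% of null samples), a classical
one-way ANOVA across the four conditions (F defined as 0 with p = 1 when
all values are identical), and all six pairwise *paired* t-tests —
subjects are matched across conditions by design — declared significant
at p < α/6. The Bonferroni factor spans the six pairs within one index;
correcting additionally across the eight indices (×48) is stricter and
available by passing `m = 48`.

# Reproducibility and problem sizes

Every random stage descends deterministically from one master seed;
per-recording seeds are fixed integer hashes of (cohort seed, subject,
trial, condition, channel), so any single recording can be regenerated in
isolation and an identical configuration reproduces the cohort
bit-for-bit. The default experiment — 16 subjects × 12 trials × 4
conditions = 768 recordings, 240 s ECG at 256 Hz and 124 s EDA at 8 Hz
per recording, full 255-subset search for all seven classifiers —
completes in a few minutes on one CPU; the test suite works on smaller
cohorts except where the full design itself is under test.

# Known limitations

The deconvolution driver lives on the 8 Hz sample grid, so SCR onsets are
quantized to 125 ms; events closer than ~1 s merge. The spline tachogram
attenuates oscillations near the Nyquist of the beat sampling itself, so
LF/HF ratios are validated against a simulation oracle rather than
against the analytic modulation ratio. The KS screen inherits the
estimated-parameter caveat above. QDA needs more samples per class than
features and will error (by design) on small cohorts with the full
8-feature set.
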