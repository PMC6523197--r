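# ansid — task identification from HRV and EDA

`ansid` is an R package for psychophysiologists and biomedical-signal
researchers who want to ask: *can the task a person is performing be read
off their autonomic nervous system?* It implements the full analysis
chain for a four-condition protocol — rest baseline (BL), psychomotor
vigilance (PVT), auditory working memory (n-back), and visual ship search
(SS):

1. **HRV indices from ECG** — band-pass filtering (0.05–40 Hz), R-peak
   detection, cubic-spline resampling of the RR tachogram to 4 Hz, an
   averaged 256-point Blackman periodogram, and band powers
   HRV<sub>LF</sub> (0.045–0.15 Hz), HRV<sub>HF</sub> (0.15–0.4 Hz) plus
   their total-power-normalized forms.
2. **EDA indices from skin conductance** — a non-negative sparse
   deconvolution splits the signal into a slow tonic curve and a sparse
   phasic driver convolved with a Bateman kernel
   (h(t) = e<sup>−t/10</sup> − e<sup>−t/0.75</sup>), giving SCL (tonic
   mean) and NS.SCRs (reconstructed responses above 0.05 µS, per minute);
   EDASymp is Welch band power over 0.045–0.25 Hz; TVSymp is the mean
   instantaneous amplitude of the 0.08–0.24 Hz components of a complex
   demodulation bank.
3. **Classification** — seven classifiers (1-NN; linear and Gaussian SVM
   with C = 1, γ = 2.6; CART; LDA; QDA; Mahalanobis-QDA) under
   leave-one-subject-out cross-validation, with exhaustive search over
   all 2⁸ − 1 = 255 feature subsets, confusion matrices, and a
   temporal-generalization analysis (train on trial 1, test on trials
   2–12).
4. **Group statistics** — KS normality screen, one-way ANOVA per index,
   and Bonferroni-corrected paired pairwise tests with the conventional
   `* † ‡` significance markers.

Because no human recordings ship with the package, a synthetic-cohort
generator provides labelled ECG/EDA with ground truth: beat times from an
integral pulse frequency modulation model (a beat at each unit crossing
of the integral of the LF/HF-modulated heart rate) and skin conductance
from a tonic curve plus a Poisson train of Bateman-kernel responses.
Condition profiles default to the published summary statistics of a
16-subject, 12-trial wakefulness study (e.g. SCL 0.19 / 3.5 / 4.6 /
5.6 µS across BL / PVT / n-back / SS), and every extraction stage is
tested against the generator's truth records. See
`vignettes/methods.Rmd` for the model details and design decisions.

## Worked example

```r
library(ansid)

profiles <- default_condition_profiles()

# one ship-search recording: simulate, then extract
sim <- generate_rr(profiles$SS, duration = 244, seed = 7)
ecg <- synthesize_ecg(sim$rr, fs = 256, seed = 7, duration = 244)
str(hrv_features(ecg)[1:5])
#> List of 5
#>  $ HRVLF      : num 3630
#>  $ HRVHF      : num 1357
#>  $ HRVLFn     : num 0.449
#>  $ HRVHFn     : num 0.168
#>  $ total_power: num 8078

eda <- synthesize_eda(profiles$SS, duration = 124, seed = 7)
unlist(eda_features(eda$eda))
#>        SCL    NS_SCRs    EDASymp     TVSymp
#> 5.61305463 2.00000000 0.01120051 0.47972445
```

The HRV values say this recording carried about 2.7× more LF than HF
power (sympathetic-leaning balance, as configured for ship search), and
the EDA values sit where the SS profile puts them: a tonic level near
5.6 µS, two supra-threshold skin conductance responses per minute, and a
TVSymp of ~0.48 in normalized units.

```r
# a small labelled cohort end to end
ft <- cohort_features(n_subjects = 4, n_trials = 1, seed = 1)
loso_cv(ft, classifier_spec("KNN"))
#> <cv_result> KNN on {SCL, NS_SCRs, EDASymp, TVSymp, HRVLF, HRVLFn, HRVHF, HRVHFn}: accuracy 37.5% (16 samples)
#>        predicted
#> true    BL PVT NBACK SS
#>   BL     1   1     1  1
#>   PVT    0   2     1  1
#>   NBACK  0   1     2  1
#>   SS     1   0     2  1
```

With only 4 subjects the between-subject variance dominates and LOSO
accuracy is modest; the default 16-subject cohort classifies far better
(run `run_experiment(run_config())`, which writes the feature table, the
comparison report, the subset-search ranking, confusion matrices and the
per-trial temporal accuracies to its output directory).

A thin CLI over the same functions lives at `inst/cli/ansid.R`
(`simulate`, `extract`, `compare`, `classify`, `search`, `temporal`,
`run-all`).

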