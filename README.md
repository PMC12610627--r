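# trustfuse

Multimodal assessment of a person's situational **trust in an assistive
device** during lower-limb rehabilitation training, for researchers in
psychophysiology, rehabilitation engineering and human–robot interaction.

Three synchronized streams are scored onto one 1–10 trust scale and then
fused:

- **EEG**: the alpha/beta spectral power ratio per decision-point epoch.
  After zero-phase 1–45 Hz band-pass filtering, db4 wavelet denoising and
  median filtering, Welch band powers are computed on 3 s epochs
  (−1 to +2 s around each decision point), ratios are standardized across
  the recording's epochs, `Z = (X − μ)/σ`, and mapped by

  ```
  score = 5 + 2.5 · tanh(Z)
  ```

  so a mean epoch scores 5 and all scores lie in (2.5, 7.5).
- **Questionnaire**: 12 ten-point Likert items (items 1–3 reverse-keyed),
  averaged; Cronbach's α for internal consistency.
- **Behavior** (ground truth): adherence %, decision latency, reliance,
  intervention and verification counts mapped monotonically to a 0–10
  score.

The EEG and questionnaire scores are fused by a first-order
**Takagi–Sugeno ANFIS** (2 Gaussian sets per input, the full 2×2 rule
grid, product t-norm) trained against the behavioral score with hybrid
learning — exact least squares for the 12 consequent coefficients, one
gradient step per epoch on the membership parameters — and evaluated by
leave-one-participant-out cross-validation. A validation battery compares
the four modalities: per-modality variances and Shapiro–Wilk tests,
Kruskal–Wallis H with ε² = H/(n−1) and Dunn–Bonferroni post hocs, the
Pearson/Spearman/Kendall correlation triad against behavior, Cohen's κ of
Low/Middle/High trust classifications, bootstrap tests of pairwise κ
differences, and the EEG-vs-questionnaire confusion matrix.

Because the underlying human dataset is not public, the package ships a
**synthetic cohort generator** that emulates the study's structure — 21
participants × 3 scenarios with latent trust trajectories, EEG whose α/β
ratio rises with trust plus EMG/motion artifacts, biased questionnaire
responses and behavior ≈ latent trust — so the entire pipeline is testable
end to end. See `vignettes/trustfuse-methods.Rmd` for the models and every
tunable default.

## Worked example

```r
library(trustfuse)

report <- run_pipeline(cohort_config(), seed = 1)
print(report)
#> <trust_report> seed 1, 504 aligned events, 13.9 s
#>  LOOCV: RMSE 0.651, R^2 0.746
#>  correlations vs behavior:
#>       modality   pearson  spearman   kendall
#>            eeg 0.5295728 0.5460259 0.3869639
#>  questionnaire 0.8410471 0.8698388 0.6923670
#>          fused 0.8816522 0.8840200 0.7039351
#>  kappa vs behavior:
#>       modality       kappa      p_value
#>            eeg  0.33070032 1.709393e-23
#>  questionnaire -0.04345844 2.884688e-05
#>          fused  0.59900854 2.170292e-71

report$validation$dispersion$variances
#>   modality      variance
#> 1 eeg               2.37
#> 2 questionnaire     1.13
#> 3 fused             1.30
#> 4 behavior          1.67
```

Reading those numbers: the EEG score is the most dispersed modality
(variance 2.37 vs 1.13 for the questionnaire) and tracks behavior at
ρ ≈ 0.55 — temporally sensitive but noisy. The questionnaire ranks events
well (ρ ≈ 0.87) yet its social-desirability inflation shifts its absolute
level so badly that its classification agreement with behavior collapses
(κ ≈ 0). The ANFIS fusion dominates both inputs on every metric
(ρ ≈ 0.88, κ ≈ 0.60): the package's central claim, that fusing a
temporally precise but artifact-prone signal with a stable but biased one
beats either alone, is visible directly in the report.

Useful building blocks:

```r
co    <- simulate_cohort(config = cohort_config_clean(), seed = 7)
rec   <- co$recordings[[1]]
ev    <- dplyr::filter(co$events, participant == "P01",
                       scenario == "cane_walker")
curve <- compute_trust_curve(rec, ev)   # per-epoch EEG trust scores
autoplot(curve)

fit <- anfis_fit(report$score_table, epochs = 100)
tidy(fit); glance(fit); autoplot(fit)   # parameters, fit summary, surface
```

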