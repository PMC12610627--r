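---
title: "Multimodal trust assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal trust assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustfuse)
```

`trustfuse` estimates a person's situational trust in an assistive device
from three synchronized data streams — single-channel EEG, a 12-item Likert
questionnaire, and observational behavioral coding — and fuses the EEG and
questionnaire scores with an adaptive neuro-fuzzy inference system (ANFIS),
using the behavioral score as ground truth. This vignette explains the
models behind each stage, the parameters a user might want to change, what
the synthetic cohort generator does and does not emulate, and the design
decisions we made where the methodology left genuine choices open.

## The EEG trust score

The neural marker is the alpha/beta spectral power ratio: alpha power
(8–13 Hz) rises with calm, relaxed engagement, while beta power (13–30 Hz)
rises with vigilance and effortful monitoring, so their ratio increases
with trust in the device.

The scoring pipeline for one recording is:

1. **Preprocessing.** A zero-phase (forward–backward) FIR band-pass at
   1–45 Hz removes drift and high-frequency noise; Daubechies-4 wavelet
   denoising (5 levels, soft universal threshold, noise scale estimated
   from the finest detail level's median absolute deviation) and a
   5-sample median filter suppress transient artifacts.
2. **Baseline.** The alpha/beta ratio of the first 10 s resting segment is
   computed and stored with the curve as the individual reference state.
3. **Epoching.** Around each annotated decision point, a 3 s epoch
   (−1 to +2 s) is cut from the task segment; epochs that do not fit are
   skipped with a warning.
4. **Band power.** Welch's method (2 s Hann windows, 50% overlap; 1000
   samples per window at 500 Hz) estimates the PSD per epoch; band powers
   are trapezoidal integrals of the PSD over the band limits.
5. **Scoring.** The epoch ratios \(X\) are standardized across the
   recording's task epochs, \(Z = (X - \mu)/\sigma\), and mapped onto the
   trust scale by \(\mathrm{score} = 5 + 2.5\tanh Z\). A mean epoch
   (\(Z = 0\)) scores exactly 5; all scores lie in the open interval
   (2.5, 7.5); typical epochs (\(Z \approx \pm 2\)) land near 3–8, which
   avoids floor and ceiling effects.

Two statements about normalization coexist in the underlying methodology:
standardization against the resting baseline, and standardization by the
mean and standard deviation of *all task epoch ratios*. These are not the
same operation. We implement the epoch-set standardization (it is the one
given as an explicit formula) and surface the baseline ratio as metadata on
every `trust_curve`, so a baseline-relative analysis remains a one-liner
for the user. Relatedly, the \(\tanh\) mapping cannot produce scores of 8
or 9 out of 10 even though such values are sometimes quoted for EEG trust
scores elsewhere; we keep the mapping exact and note the discrepancy
rather than rescaling.

Other numerical choices: FIR filters are Hamming-windowed sinc designs with
a transition bandwidth of 25% of the lower cut-off **floored at 2 Hz**
(a 0.25 Hz transition at the 1 Hz edge would require ~6600 taps for no
practical gain; the 2 Hz floor matches common EEG-software defaults),
orders rounded up to odd; filtering is applied forward and backward by FFT
convolution with odd-reflection edge padding, so the response is exactly
zero-phase. Band powers for scoring are always integrated from the
broadband Welch PSD; the five FIR band-limited series from
`band_decompose()` exist for quality control (e.g. spotting delta-band
artifact load), not for scoring — the PSD path is the quantitatively
specified one. Epochs whose beta power falls below \(10^{-12}\,\mu V^2\)
are flagged invalid instead of producing unbounded ratios, and a recording
whose epoch ratios have zero dispersion raises a degenerate-input error
rather than silently scoring 5 everywhere.

## Questionnaire and behavioral scores

The questionnaire has 12 ten-point Likert items. Items 1–3 are
distrust-phrased ("negative consequences", "must be cautious", "risky"),
so they are reverse-scored as \(11 - v\); the keying lives in one
function (`reverse_keyed_items()`) because the original instrument does
not state it and a user may wish to audit or change it. The trust score is
the unweighted mean of the keyed items — a mean rather than a sum so the
result stays on the same 1–10 scale as the EEG score and can be fused
without rescaling. Internal consistency is measured with Cronbach's
\(\alpha\) on the keyed item matrix.

Behavioral coding provides five indicators per decision point: instruction
adherence (%), decision latency (s), device reliance, intervention and
verification counts. Each maps to a normalized sub-score in \([0, 1]\) —
`adherence/100`, `exp(-latency/tau)`, `1/(1 + count/c)` — and the trust
score is ten times their mean. The scale constants default to
\(\tau = 5\) s and \(c = 3\) events; the original scoring scale is
described only as "predefined", so these are package defaults, exposed via
`behavior_norms()`. All sub-scores are monotone ("fewer interventions and
successful completion indicate higher trust"), and the score spans exactly
0–10 at the extremes.

## ANFIS fusion

The fusion model is a first-order Takagi–Sugeno system with two inputs
(EEG and questionnaire scores, fed on their native 1–10 scale), two
Gaussian membership functions per input ("Low", "High"), and the full
2×2 rule grid:

| Rule | EEG | Questionnaire | Output |
|------|-----|---------------|--------|
| 1 | Low | Low | \(p_1 = a_1 x_E + b_1 x_Q + d_1\) |
| 2 | Low | High | \(p_2\) |
| 3 | High | Low | \(p_3\) |
| 4 | High | High | \(p_4\) |

Rule strength is the product of the two memberships; the output is the
normalized weighted sum of the four linear consequents. Normalization is
done in log space so that inputs far outside the membership support cannot
underflow the weights to an all-zero vector. Four rules (not more) is a
deliberate parsimony choice given cohorts of ~21 participants.

**Initialization.** "Low"/"High" centers start at the 25th/75th
percentiles of each input's training values; both widths start at half the
center separation (floored at \(10^{-3}\)); consequents start flat at the
mean target. **Hybrid learning** alternates, each epoch, (i) an exact
least-squares solve of the 12 consequent coefficients on the
strength-weighted design matrix with the premise frozen (ridge
\(\lambda = 10^{-8}\) fallback if singular), and (ii) one full-batch
gradient step (`lr = 0.01`, analytic gradients) on the centers and widths.
The schedule runs 100 epochs by default and the returned model carries the
parameters with the lowest training RMSE seen. The learning rate, epoch
count and seed are recorded in the model's config.

Generalization is assessed by leave-one-**participant**-out
cross-validation: folds are grouped, never per-row, because rows within a
participant share latent structure and per-row folding would leak it. We
report pooled RMSE and \(R^2 = 1 - SSE/SST\). On the reference human
cohort this evaluation was reported as RMSE 1.17 and \(R^2\) 0.78; those
numbers depend on data that is not public, so here they serve only as a
sanity scale for the synthetic-cohort results, never as an assertion.

## Statistical validation

`validate_modalities()` reproduces the full comparison battery on an
aligned per-event score table:

- **Dispersion.** Shapiro–Wilk per modality (motivating non-parametrics),
  per-modality variances, Kruskal–Wallis H across the four modalities with
  tie correction, effect size \(\varepsilon^2 = H/(n-1)\) (the formula was
  not stated in the source methodology; this is the standard rank
  epsilon-squared), Dunn's post hoc z-tests with Bonferroni over the six
  pairs, and a complementary one-way ANOVA.
- **Correlation.** Pearson's r, Spearman's \(\rho\) and Kendall's
  \(\tau_b\) of each modality against behavior.
- **Classification agreement.** Scores are cut into Low/Middle/High at
  4.5 and 7.0. These thresholds are reverse-engineered from narrated
  cases (4/10 described as low, 5–6.5 as moderate, 8–9 as high) and are
  overridable, including an empirical-tertile mode. Cohen's \(\kappa\) of
  each modality against behavior is reported with a large-sample p-value.
  No standard test is named anywhere for comparing two dependent kappas,
  so the pairwise \(\kappa\) differences are tested by a paired percentile
  bootstrap (resample analysis units, recompute both kappas, two-sided
  percentile p; B = 2000, seeded), Bonferroni-corrected across the three
  pairs. The EEG-vs-questionnaire confusion matrix is emitted in counts
  and row percentages.

The unit of analysis is one row per participant × scenario × decision
point; per-participant summaries can be built from the same table with
one `dplyr::summarise()`.

## The synthetic cohort generator

No human dataset ships with the package, so every downstream stage is
exercised against a generator that emulates the study's data structure: 21
participants, three scenarios (cane/walker course, stairs, handrail path)
of graded difficulty, and — by default — 8 decision points per scenario
(the true count per scenario is not documented; 8 is an arbitrary,
configurable default).

- **Latent trust** is the scenario difficulty level
  (\(0.8 - 0.5 \cdot \mathrm{difficulty}\)) plus a session-centred,
  reflected Ornstein–Uhlenbeck fluctuation (innovation sd 0.11, reversion
  0.3 by default). Centring the fluctuation within a session makes the
  session mean a function of difficulty alone, which keeps per-session
  z-standardized EEG scores comparable across sessions. True trust is
  never observable in the real study — behavior is its proxy — so the
  generator makes the behavioral score approximately \(10\times\) latent
  trust by construction.
- **EEG** is a two-oscillator mixture: a 10 Hz alpha tone and a 20 Hz
  beta tone whose powers are calibrated so that the alpha/beta power
  ratio is *linear* in latent trust (\(0.5 + 2u\), with alpha power
  rising and beta power falling in \(u\)), over a 1/f background.
  Linearity keeps per-session z-scores on a common footing across
  sessions; any strictly monotone link would preserve within-session
  rank recovery. Artifacts are EMG-like bursts (band-limited 20–45 Hz
  carriers under 200 ms Tukey envelopes, Poisson-scheduled, default
  4/min at 20 µV) and motion-like transients (0.8 s half-sine pulses,
  default 2/min at 30 µV) — both chosen to be separable, in part, by the
  1–45 Hz + wavelet cleaning chain.
- **Questionnaire** items are
  \(\mathrm{clip}(\mathrm{round}(1 + 9(u + \mathrm{bias}) +
  \mathcal N(0, \sigma)), 1, 10)\) with round-half-up discretization
  (stated once, tested once), items 1–3 stored inverted. The
  social-desirability bias is drawn once per participant
  (\(\mathcal N(0.3, 0.08)\) by default): a positive bias both inflates
  the questionnaire mean and, through ceiling saturation, compresses its
  variance — the mechanism behind the "stable but biased" questionnaire
  pattern. The default bias strength was chosen so that saturation is
  clearly visible in a cohort of this size.
- **Behavior** indicators are monotone transforms of latent trust with
  small independent noise (sd 0.05 on the latent scale).

`cohort_config_clean()` is the diagnostic configuration: artifacts, bias
and noise off, a common difficulty, and wider latent excursions
(innovation sd 0.22) so the trajectory spans the trust scale and the
Likert discretization resolves distinct levels. Under it, every modality's
pooled per-event score rank-correlates with latent trust above 0.9, and
the modalities agree with one another above 0.95 — this is what "the
pipeline is faithful" means here.

What the generator does **not** emulate: multichannel EEG, volume
conduction or any head-model physics, realistic EEG spectra beyond the
two tones + 1/f, non-stationary artifact statistics, questionnaire item
heterogeneity (all 12 items share one latent driver, so Cronbach's
\(\alpha\) is high by construction and the reported human value of 0.82
cannot be reproduced or falsified here), or coder disagreement in the
behavioral scores. Tests passing on this cohort show the *pipeline* is
correct and the *statistical machinery* behaves as designed; they do not
show that the trust model holds in real patients.

## Problem sizes and reproducibility

All randomness descends from a single integer seed through named
substreams, so cohorts, fits and bootstrap analyses are bit-reproducible;
`write_cohort()` output is byte-identical across runs with the same seed.
The test suite exercises the default cohort geometry (21 × 3 × 8 events);
the structural-findings check aggregates 50 cohort replicates, and the
planted-model ANFIS recovery uses 63 triples (21 participants × 3), the
size the grouped LOOCV is designed around. `scripts/acceptance.R`
recomputes the analytic reference value of the score mapping from the
installed package.

## Known limitations

- The wavelet denoiser's universal threshold is estimated from the finest
  detail level; after 1–45 Hz band-limiting that level is nearly empty,
  so the denoiser is intentionally conservative and most artifact
  suppression comes from the band-pass and median filter. Level-dependent
  thresholds were evaluated and rejected: they shrink genuine alpha/beta
  oscillations enough to destroy trust-ordering recovery.
- EEG scores are standardized per recording, so between-session level
  differences are not comparable across sessions by design; pooled
  analyses rely on the latent fluctuations dominating session effects.
- The kappa-difference bootstrap treats analysis units as exchangeable
  rows; it does not model the participant hierarchy.
- Scores from Eq.-style \(\tanh\) mapping can never reach the nominal
  1–10 extremes; classification thresholds were chosen with that range in
  mind.
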