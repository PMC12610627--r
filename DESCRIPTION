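Package: trustfuse
Title: Multimodal Trust Assessment from EEG, Questionnaire and Behavioral
    Data via Neuro-Fuzzy Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating situational trust in assistive-device use
    from synchronized multimodal recordings. Implements an EEG trust score
    based on the alpha/beta spectral power ratio (zero-phase band-pass
    filtering, db4 wavelet denoising, Welch band power, z-standardization and
    a bounded tanh mapping onto a 1-10 scale), Likert questionnaire scoring
    with reverse keying and Cronbach's alpha, behavioral trust scoring from
    observational coding counts, and a first-order Takagi-Sugeno adaptive
    neuro-fuzzy inference system (ANFIS) with hybrid least-squares/gradient
    learning that fuses the EEG and questionnaire scores against behavioral
    ground truth. Includes a synthetic cohort generator with controllable
    EMG/motion artifact contamination and social-desirability bias, and a
    validation suite (Kruskal-Wallis with epsilon-squared, Dunn post hoc,
    correlation triad, Cohen's kappa agreement and confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
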