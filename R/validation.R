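# Dispersion, correlation and classification-agreement analyses comparing
# the EEG, questionnaire and fused trust scores against the behavioral
# benchmark.

modality_levels <- function() c("eeg", "questionnaire", "fused", "behavior")

check_score_table <- function(table, cols = modality_levels()) {
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop_invalid(
      paste0("Score table lacks column(s): ", paste(missing, collapse = ", ")),
      "trustfuse_validation_error"
    )
  }
  invisible(table)
}

#' Dispersion analysis of the four trust modalities
#'
#' Per-modality Shapiro-Wilk normality tests and sample variances, a
#' tie-corrected Kruskal-Wallis H test across modalities with the
#' epsilon-squared effect size `H / (n - 1)`, Dunn's post hoc pairwise
#' z-tests with Bonferroni correction, and a complementary one-way ANOVA.
#'
#' @param table Data frame with numeric columns `eeg`, `questionnaire`,
#'   `fused`, `behavior` (one row per analysis unit).
#'
#' @return A list: `normality` (tibble), `variances` (tibble),
#'   `kruskal` (`H`, `df`, `p_value`, `epsilon_squared`, `n`),
#'   `dunn` (tibble of pairwise z tests with raw and Bonferroni-adjusted p),
#'   `anova` (`F`, `df1`, `df2`, `p_value`).
#' @export
dispersion_analysis <- function(table) {
  check_score_table(table)
  long <- tidyr::pivot_longer(
    table[modality_levels()],
    dplyr::everything(),
    names_to = "modality", values_to = "score"
  ) |>
    dplyr::mutate(modality = factor(.data$modality, levels = modality_levels()))
  if (any(table(long$modality) < 5)) {
    stop_invalid("Need >= 5 observations per modality.", "trustfuse_invalid_argument")
  }
  if (sd(long$score) == 0) {
    stop_invalid("All scores identical; dispersion analysis degenerate.", "trustfuse_degenerate_input")
  }
  normality <- long |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(
      w = shapiro.test(.data$score)$statistic,
      p_value = shapiro.test(.data$score)$p.value,
      .groups = "drop"
    )
  variances <- long |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(variance = var(.data$score), .groups = "drop")
  kw <- kruskal.test(score ~ modality, data = long)
  n <- nrow(long)
  aov_fit <- oneway.test(score ~ modality, data = long, var.equal = TRUE)
  list(
    normality = normality,
    variances = variances,
    kruskal = list(
      H = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value,
      epsilon_squared = unname(kw$statistic) / (n - 1),
      n = n
    ),
    dunn = dunn_test(long$score, long$modality),
    anova = list(
      F = unname(aov_fit$statistic),
      df1 = unname(aov_fit$parameter[1]), df2 = unname(aov_fit$parameter[2]),
      p_value = aov_fit$p.value
    )
  )
}

#' Dunn's post hoc pairwise z-tests on ranks
#'
#' Pairwise mean-rank comparisons following a Kruskal-Wallis test, with the
#' standard tie correction and Bonferroni adjustment across all pairs.
#'
#' @param x Numeric response vector.
#' @param g Grouping factor.
#'
#' @return Tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(x, g) {
  g <- droplevels(as.factor(g))
  n <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  sizes <- table(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  res <- purrr::map_dfr(seq_len(m), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    tibble::tibble(group1 = a, group2 = b, z = z, p_value = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- pmin(1, res$p_value * m)
  res
}

#' Correlation triad of each modality against the behavioral benchmark
#'
#' Pearson's r (linear), Spearman's rho (monotonic) and Kendall's tau-b
#' (tie-corrected concordance) for the EEG, questionnaire and fused score
#' columns against the behavioral column.
#'
#' @inheritParams dispersion_analysis
#' @return Tibble: `modality`, `pearson`, `spearman`, `kendall`.
#' @export
correlation_analysis <- function(table) {
  check_score_table(table)
  if (nrow(table) < 3L) {
    stop_invalid("Need >= 3 paired observations.", "trustfuse_invalid_argument")
  }
  y <- table$behavior
  purrr::map_dfr(c("eeg", "questionnaire", "fused"), function(mod) {
    x <- table[[mod]]
    if (sd(x) == 0 || sd(y) == 0) {
      stop_invalid(
        sprintf("Zero variance in `%s` or `behavior`; correlation undefined.", mod),
        "trustfuse_degenerate_input"
      )
    }
    tibble::tibble(
      modality = mod,
      pearson = cor(x, y),
      spearman = cor(x, y, method = "spearman"),
      kendall = cor(x, y, method = "kendall")
    )
  })
}

#' Classify trust scores into Low / Middle / High levels
#'
#' Thresholds on the common 1-10 scale: Low below `low`, High at or above
#' `high`, Middle in between. Defaults (4.5 and 7.0) place a score of 4 in
#' Low, 5-6.5 in Middle and 8-9 in High; `mode = "tertile"` instead cuts at
#' the empirical tertiles of the supplied scores.
#'
#' @param score Numeric vector of trust scores.
#' @param low,high Fixed thresholds (used when `mode = "fixed"`).
#' @param mode `"fixed"` or `"tertile"`.
#'
#' @return Ordered factor with levels `Low < Middle < High`.
#' @export
#' @examples
#' classify_trust(c(4, 5, 8))
classify_trust <- function(score, low = 4.5, high = 7.0, mode = c("fixed", "tertile")) {
  mode <- match.arg(mode)
  if (!all(is.finite(score))) {
    stop_invalid("Scores must be finite.", "trustfuse_invalid_argument")
  }
  if (mode == "tertile") {
    qs <- quantile(score, c(1 / 3, 2 / 3), names = FALSE)
    low <- qs[1]
    high <- qs[2]
  }
  lev <- c("Low", "Middle", "High")
  factor(
    ifelse(score < low, "Low", ifelse(score < high, "Middle", "High")),
    levels = lev, ordered = TRUE
  )
}

#' Confusion matrix between two modality label columns
#'
#' @param labels_a,labels_b Factors with identical level sets; `labels_a`
#'   indexes the rows.
#' @return A list: `counts` (matrix) and `row_pct` (row-normalized
#'   percentages; all-zero rows stay zero).
#' @export
confusion_matrix <- function(labels_a, labels_b) {
  counts <- table(labels_a, labels_b)
  rs <- rowSums(counts)
  row_pct <- sweep(counts, 1, ifelse(rs == 0, 1, rs), "/") * 100
  list(counts = unclass(counts), row_pct = unclass(row_pct))
}

#' Agreement analysis of trust-level classifications across modalities
#'
#' Computes Cohen's kappa of each modality's trust levels against the
#' behavioral levels (with large-sample p-values), tests pairwise kappa
#' differences by a paired percentile bootstrap over analysis units
#' (Bonferroni-corrected across the three pairs), and builds the
#' EEG-vs-questionnaire confusion matrix in counts and row percentages.
#'
#' @param levels_table Data frame with factor columns `eeg`,
#'   `questionnaire`, `fused`, `behavior` holding Low/Middle/High labels
#'   (e.g. from [classify_trust()]).
#' @param n_boot Bootstrap replicates for the kappa-difference tests.
#' @param seed Integer seed for the bootstrap.
#'
#' @return A list of class `trust_agreement`: `kappa` (tibble `modality`,
#'   `kappa`, `p_value`), `kappa_differences` (tibble with bootstrap
#'   two-sided p, raw and Bonferroni), `confusion` (counts + row_pct,
#'   EEG rows vs questionnaire columns).
#' @export
agreement_analysis <- function(levels_table, n_boot = 2000, seed = 1) {
  check_score_table(levels_table)
  mods <- c("eeg", "questionnaire", "fused")
  kap <- purrr::map_dfr(mods, function(mod) {
    k <- interrater_kappa(levels_table[[mod]], levels_table$behavior)
    tibble::tibble(modality = mod, kappa = k$kappa, p_value = k$p_value)
  })
  pairs <- utils::combn(mods, 2)
  n <- nrow(levels_table)
  diffs <- with_seed(derive_seed(seed, "kappa_boot"), {
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]
      b <- pairs[2, j]
      obs <- kap$kappa[kap$modality == a] - kap$kappa[kap$modality == b]
      boot <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        ka <- tryCatch(
          interrater_kappa(levels_table[[a]][idx], levels_table$behavior[idx])$kappa,
          error = function(e) NA_real_
        )
        kb <- tryCatch(
          interrater_kappa(levels_table[[b]][idx], levels_table$behavior[idx])$kappa,
          error = function(e) NA_real_
        )
        ka - kb
      }, numeric(1))
      boot <- boot[is.finite(boot)]
      # two-sided percentile p: how often the bootstrapped difference
      # crosses zero
      p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
      tibble::tibble(
        modality_a = a, modality_b = b,
        kappa_difference = obs, p_value = min(1, p)
      )
    })
  })
  diffs$p_adjusted <- pmin(1, diffs$p_value * ncol(pairs))
  structure(
    list(
      kappa = kap,
      kappa_differences = diffs,
      confusion = confusion_matrix(levels_table$eeg, levels_table$questionnaire)
    ),
    class = "trust_agreement"
  )
}

#' @export
print.trust_agreement <- function(x, ...) {
  cat("<trust_agreement>\n kappa vs behavior:\n")
  print(as.data.frame(x$kappa), row.names = FALSE)
  cat(" EEG x questionnaire confusion (row %):\n")
  print(round(x$confusion$row_pct, 1))
  invisible(x)
}

#' Validate a modality score table end to end
#'
#' Runs the dispersion, correlation and (after classification) agreement
#' analyses on an aligned per-event score table.
#'
#' @inheritParams dispersion_analysis
#' @param thresholds Length-2 numeric, Low/High classification cut points.
#' @param n_boot,seed Passed to [agreement_analysis()].
#'
#' @return A list of class `trust_validation`: `dispersion`, `correlation`,
#'   `agreement`, `levels` (the classified table).
#' @export
validate_modalities <- function(table, thresholds = c(4.5, 7.0),
                                n_boot = 2000, seed = 1) {
  check_score_table(table)
  disp <- dispersion_analysis(table)
  corr <- correlation_analysis(table)
  lv <- table
  for (mod in modality_levels()) {
    lv[[mod]] <- classify_trust(table[[mod]], low = thresholds[1], high = thresholds[2])
  }
  agr <- agreement_analysis(lv, n_boot = n_boot, seed = seed)
  structure(
    list(dispersion = disp, correlation = corr, agreement = agr, levels = lv),
    class = "trust_validation"
  )
}

#' @export
print.trust_validation <- function(x, ...) {
  k <- x$dispersion$kruskal
  cat(sprintf(
    "<trust_validation> Kruskal-Wallis H(%d) = %.2f, p = %.3g, eps^2 = %.3f\n",
    k$df, k$H, k$p_value, k$epsilon_squared
  ))
  cat(" correlations vs behavior:\n")
  print(as.data.frame(x$correlation), row.names = FALSE)
  print(x$agreement)
  invisible(x)
}
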