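toy_table <- function(n = 40, seed = 61) {
  set.seed(seed)
  u <- runif(n, 0, 1)
  tibble::tibble(
    eeg = trustfuse::zscore_to_trust(scale(u)[, 1] + rnorm(n, 0, 0.8)),
    questionnaire = pmin(pmax(1 + 9 * (u + 0.2) + rnorm(n, 0, 0.7), 1), 10),
    fused = 1 + 9 * u + rnorm(n, 0, 0.4),
    behavior = 10 * u + rnorm(n, 0, 0.3)
  )
}

test_that("Kruskal-Wallis H matches the brute-force rank evaluation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(oracle_kruskal_h(x, g), 7.2)
  expect_equal(unname(kruskal.test(x, factor(g))$statistic), 7.2)

  set.seed(62)
  for (i in 1:5) {
    xx <- sample(1:8, 40, replace = TRUE) # heavy ties on purpose
    gg <- sample(c("a", "b", "c", "d"), 40, replace = TRUE)
    expect_equal(
      unname(kruskal.test(xx, factor(gg))$statistic),
      oracle_kruskal_h(xx, gg),
      tolerance = 1e-10
    )
  }
})

test_that("dispersion analysis reports H, epsilon-squared, Dunn and ANOVA coherently", {
  tab <- toy_table()
  res <- dispersion_analysis(tab)
  n <- 4 * nrow(tab)
  expect_equal(res$kruskal$n, n)
  expect_equal(res$kruskal$epsilon_squared, res$kruskal$H / (n - 1))
  expect_equal(nrow(res$dunn), 6)
  expect_true(all(res$dunn$p_adjusted >= res$dunn$p_value)) # Bonferroni never lowers p
  expect_true(all(res$dunn$p_adjusted <= 1))
  expect_equal(nrow(res$normality), 4)
  expect_true(res$anova$p_value >= 0 && res$anova$p_value <= 1)

  long_h <- oracle_kruskal_h(
    c(tab$eeg, tab$questionnaire, tab$fused, tab$behavior),
    rep(c("eeg", "questionnaire", "fused", "behavior"), each = nrow(tab))
  )
  expect_equal(res$kruskal$H, long_h, tolerance = 1e-10)
})

test_that("identical score distributions give H = 0 and all Dunn p = 1", {
  block <- rep(c(2, 4, 6, 8, 9), 2)
  tab <- tibble::tibble(
    eeg = block, questionnaire = block, fused = block, behavior = block
  )
  res <- dispersion_analysis(tab)
  expect_equal(res$kruskal$H, 0)
  expect_true(all(res$dunn$p_adjusted == 1))
})

test_that("the Kruskal-Wallis statistic is invariant under monotone transforms", {
  tab <- toy_table(seed = 63)
  h1 <- dispersion_analysis(tab)$kruskal$H
  tab2 <- dplyr::mutate(tab, dplyr::across(dplyr::everything(), ~ exp(.x / 3)))
  h2 <- dispersion_analysis(tab2)$kruskal$H
  expect_equal(h1, h2, tolerance = 1e-10)
})

test_that("the correlation triad captures linear and monotone structure", {
  x <- c(-2, -1, 0, 1, 2)
  tab <- tibble::tibble(eeg = x, questionnaire = x, fused = x^3, behavior = x)
  res <- correlation_analysis(tab)
  eeg_row <- res[res$modality == "eeg", ]
  expect_equal(eeg_row$pearson, 1)
  expect_equal(eeg_row$spearman, 1)
  expect_equal(eeg_row$kendall, 1)
  fused_row <- res[res$modality == "fused", ]
  expect_equal(fused_row$spearman, 1)
  expect_equal(fused_row$kendall, 1)
  expect_lt(fused_row$pearson, 1)

  expect_error(
    correlation_analysis(dplyr::mutate(tab, eeg = 5)),
    class = "trustfuse_degenerate_input"
  )
})

test_that("Kendall's tau matches exhaustive pair counting, ties included", {
  set.seed(64)
  for (i in 1:8) {
    x <- sample(1:6, 25, replace = TRUE)
    y <- sample(1:6, 25, replace = TRUE)
    expect_equal(cor(x, y, method = "kendall"), oracle_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("trust levels cut at the documented thresholds", {
  expect_equal(
    as.character(classify_trust(c(4, 5, 6.5, 7, 8, 4.49, 4.5, 6.99))),
    c("Low", "Middle", "Middle", "High", "High", "Low", "Middle", "Middle")
  )
  lv <- classify_trust(c(1, 2, 3, 5, 6, 7, 8, 9, 10), mode = "tertile")
  expect_equal(as.character(table(lv)["Low"] > 0), "TRUE")
  expect_error(classify_trust(c(1, NA)), class = "trustfuse_invalid_argument")
})

test_that("row-normalized confusion percentages sum to 100 and match hand values", {
  a <- factor(rep(c("High", "Middle", "Low"), times = c(12, 4, 5)),
    levels = c("Low", "Middle", "High")
  )
  b <- factor(
    c(
      rep("High", 8), rep("Middle", 2), rep("Low", 2), # EEG High row
      rep("High", 2), rep("Middle", 2), # EEG Middle row
      "High", rep("Middle", 2), rep("Low", 2) # EEG Low row
    ),
    levels = c("Low", "Middle", "High")
  )
  cm <- confusion_matrix(a, b)
  expect_true(all(abs(rowSums(cm$row_pct) - 100) < 0.1))
  expect_equal(round(cm$row_pct["High", "High"], 1), 66.7)
  expect_equal(round(cm$row_pct["Middle", "High"], 1), 50.0)
  expect_equal(round(cm$row_pct["Middle", "Middle"], 1), 50.0)
  expect_equal(round(cm$row_pct["Low", "Middle"], 1), 40.0)
  expect_equal(round(cm$row_pct["Low", "Low"], 1), 40.0)
})

test_that("kappa from the confusion matrix equals kappa from the raw labels", {
  set.seed(65)
  a <- sample(c("Low", "Middle", "High"), 60, replace = TRUE)
  b <- sample(c("Low", "Middle", "High"), 60, replace = TRUE)
  k_raw <- interrater_kappa(a, b)$kappa
  tab <- table(factor(a), factor(b))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  expect_equal(k_raw, (po - pe) / (1 - pe), tolerance = 1e-12)
})

test_that("agreement analysis reports kappas, bootstrap differences and the confusion matrix", {
  tab <- toy_table(n = 60, seed = 66)
  lv <- tab
  for (m in names(lv)) lv[[m]] <- classify_trust(tab[[m]])
  res <- agreement_analysis(lv, n_boot = 300, seed = 1)
  expect_equal(res$kappa$modality, c("eeg", "questionnaire", "fused"))
  expect_true(all(res$kappa$kappa >= -1 & res$kappa$kappa <= 1))
  expect_equal(nrow(res$kappa_differences), 3)
  expect_true(all(res$kappa_differences$p_adjusted >= res$kappa_differences$p_value))
  expect_true(all(dim(res$confusion$counts) == c(3, 3)))

  # identical labels: kappa exactly 1 and a well-defined difference p
  lv2 <- lv
  lv2$fused <- lv2$behavior
  res2 <- agreement_analysis(lv2, n_boot = 200, seed = 2)
  expect_equal(res2$kappa$kappa[res2$kappa$modality == "fused"], 1)
  expect_true(all(is.finite(res2$kappa_differences$p_value)))
})
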