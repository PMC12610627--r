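test_that("grid initialization places centers at the quartiles", {
  set.seed(51)
  d <- tibble::tibble(
    eeg = runif(5000, 1, 10), questionnaire = runif(5000, 1, 10),
    behavior = runif(5000, 0, 10)
  )
  m <- anfis_init(d)
  expect_equal(unname(m$centers[1, ]), c(3.25, 7.75), tolerance = 0.05)
  expect_equal(unname(m$centers[2, ]), c(3.25, 7.75), tolerance = 0.05)
  expect_true(all(m$widths > 0))
  expect_equal(nrow(m$rules), 4)
  expect_setequal(paste(m$rules$eeg_set, m$rules$q_set),
                  c("Low Low", "Low High", "High Low", "High High"))

  dc <- dplyr::mutate(d, eeg = 5)
  expect_error(anfis_init(dc), class = "trustfuse_init_error")
})

test_that("the forward pass is a normalized convex combination of rule outputs", {
  d <- planted_triples(8)
  m <- anfis_init(d)
  # constant consequents: output is k everywhere
  m$consequents[, c("a", "b")] <- 0
  m$consequents[, "d"] <- 4.2
  xs <- seq(-50, 60, by = 5)
  expect_equal(anfis_forward(m, xs, rev(xs)), rep(4.2, length(xs)))

  # normalized firing strengths sum to 1 even for far-out-of-range inputs
  w <- trustfuse:::firing_strengths(m, c(1, 5.5, 1e6), c(10, 5.5, -1e6))
  expect_true(all(abs(rowSums(w) - 1) < 1e-9))

  # symmetric model, inputs midway between centers: each rule fires 0.25
  m2 <- m
  m2$centers[] <- rep(c(3, 8), each = 2)
  m2$widths[] <- 1.5
  w2 <- trustfuse:::firing_strengths(m2, 5.5, 5.5)
  expect_equal(as.numeric(w2), rep(0.25, 4))

  # tight memberships at a rule's corner: that rule dominates
  m3 <- planted_anfis()
  m3$widths[] <- 0.2
  x <- unname(m3$centers[1, "Low"])
  y <- unname(m3$centers[2, "Low"])
  p1 <- unname(m3$consequents[1, "a"] * x + m3$consequents[1, "b"] * y + m3$consequents[1, "d"])
  expect_equal(anfis_forward(m3, x, y), p1, tolerance = 1e-6)

  expect_error(anfis_forward(m, NA, 1), class = "trustfuse_invalid_argument")
})

test_that("the consequent update equals explicit least squares on the 12-column design", {
  d <- planted_triples(noise_sd = 0.5, seed = 52)
  m <- anfis_init(d)
  wbar <- trustfuse:::firing_strengths(m, d$eeg, d$questionnaire)
  got <- trustfuse:::lse_consequents(wbar, d$eeg, d$questionnaire, d$behavior)
  design <- do.call(cbind, lapply(1:4, function(r) {
    cbind(wbar[, r] * d$eeg, wbar[, r] * d$questionnaire, wbar[, r])
  }))
  want <- matrix(unname(lm.fit(design, d$behavior)$coefficients), 4, 3, byrow = TRUE)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("hybrid training fits constants exactly and tracks its best RMSE", {
  d <- planted_triples(8)
  d$behavior <- 6.5
  fit <- anfis_fit(d, epochs = 5)
  expect_lt(glance(fit)$rmse, 1e-8)
  expect_equal(predict(fit, d), rep(6.5, nrow(d)), tolerance = 1e-6)

  d2 <- planted_triples(noise_sd = 0.3, seed = 53)
  fit2 <- anfis_fit(d2, epochs = 30)
  tr <- attr(fit2, "trace")
  expect_equal(glance(fit2)$rmse, min(tr$rmse))
  expect_true(all(diff(cummin(tr$rmse)) <= 0))
  expect_error(anfis_fit(d2[1:11, ]), class = "trustfuse_invalid_argument")
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- anfis_fit(planted_triples(noise_sd = 0.2, seed = 54), epochs = 10)
  td <- tidy(fit)
  expect_equal(sum(td$component == "premise"), 8) # 2 inputs x 2 sets x (c, w)
  expect_equal(sum(td$component == "consequent"), 12)
  gl <- glance(fit)
  expect_equal(gl$nobs, 63L)
  au <- augment(fit, planted_triples(seed = 55))
  expect_true(".fused" %in% names(au))
})

test_that("grouped LOOCV makes one fold per participant and flags pure noise", {
  d <- planted_triples(6, noise_sd = 0, seed = 56)
  cv <- anfis_loocv(d, epochs = 30)
  expect_equal(cv$n_folds, 6)
  expect_equal(sort(unique(cv$predictions$group)), sort(unique(d$participant)))

  noise <- d
  set.seed(57)
  noise$behavior <- rnorm(nrow(noise), 5, 1)
  cvn <- anfis_loocv(noise, epochs = 30)
  expect_lte(cvn$r_squared, 0)

  expect_error(
    anfis_loocv(d[d$participant %in% c("P01", "P02"), ]),
    class = "trustfuse_invalid_argument"
  )
})

test_that("the fusion surface is complete, constant-consistent and slope-bounded", {
  m <- anfis_init(planted_triples(8))
  m$consequents[, c("a", "b")] <- 0
  m$consequents[, "d"] <- 3
  s <- fusion_surface(m, n = 10)
  expect_equal(nrow(s), 100)
  expect_equal(s$fused, rep(3, 100))

  fit <- planted_anfis()
  coarse <- fusion_surface(fit, n = 21)
  fine <- fusion_surface(fit, n = 201)
  # max slope estimated on the fine grid bounds adjacent coarse-grid jumps
  step_c <- 9 / 20
  step_f <- 9 / 200
  max_slope <- max(abs(diff(matrix(fine$fused, 201, byrow = TRUE)))) / step_f
  jumps <- abs(diff(matrix(coarse$fused, 21, byrow = TRUE)))
  expect_lte(max(jumps), max_slope * step_c * 1.05)
})
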