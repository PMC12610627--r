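# First-order Takagi-Sugeno ANFIS with two inputs (EEG and questionnaire
# trust scores), two Gaussian sets ("Low"/"High") per input, the fixed 2x2
# rule grid, product t-norm, normalized weighted-sum defuzzification, and
# hybrid learning (least-squares consequents + gradient premise updates).

rule_grid <- function() {
  tibble::tibble(
    rule = 1:4,
    eeg_set = c("Low", "Low", "High", "High"),
    q_set = c("Low", "High", "Low", "High")
  )
}

new_anfis <- function(centers, widths, consequents, trace = NULL, config = NULL) {
  structure(
    list(
      centers = centers, # 2x2 matrix [input, set]
      widths = widths, # 2x2 matrix [input, set], > 0
      consequents = consequents, # 4x3 matrix [rule, (a, b, d)]
      rules = rule_grid()
    ),
    trace = trace, config = config, class = "anfis"
  )
}

#' Initialize an ANFIS model from the training data
#'
#' Grid initialization: per input, the "Low" and "High" Gaussian centers are
#' placed at the 25th and 75th percentiles of that input's training values
#' and both widths are set to half the center separation (floored at 1e-3).
#' Consequents start as constants equal to the mean target, so the initial
#' surface is flat at the average fused score.
#'
#' @param data Data frame of training triples.
#' @param x_cols Names of the two input score columns (EEG first).
#' @param y_col Name of the behavioral target column.
#'
#' @return An `anfis` model object.
#' @export
anfis_init <- function(data, x_cols = c("eeg", "questionnaire"), y_col = "behavior") {
  stopifnot(length(x_cols) == 2L)
  if (nrow(data) < 4L) {
    stop_invalid("Need at least 4 training triples.", "trustfuse_invalid_argument")
  }
  centers <- matrix(NA_real_, 2, 2, dimnames = list(x_cols, c("Low", "High")))
  widths <- centers
  for (i in 1:2) {
    x <- data[[x_cols[i]]]
    qs <- quantile(x, c(0.25, 0.75), names = FALSE)
    if (diff(range(x)) == 0) {
      stop_invalid(
        sprintf("Input `%s` is constant; fuzzy sets degenerate.", x_cols[i]),
        "trustfuse_init_error"
      )
    }
    centers[i, ] <- qs
    widths[i, ] <- max((qs[2] - qs[1]) / 2, 1e-3)
  }
  consequents <- matrix(0, 4, 3, dimnames = list(NULL, c("a", "b", "d")))
  consequents[, "d"] <- mean(data[[y_col]])
  new_anfis(centers, widths, consequents,
    config = list(x_cols = x_cols, y_col = y_col)
  )
}

# Normalized firing strengths, computed in log space so that extreme inputs
# underflow gracefully; rows always sum to exactly 1.
firing_strengths <- function(model, x1, x2) {
  g <- model$rules
  logw <- matrix(0, length(x1), 4)
  for (r in 1:4) {
    c1 <- model$centers[1, g$eeg_set[r]]
    s1 <- model$widths[1, g$eeg_set[r]]
    c2 <- model$centers[2, g$q_set[r]]
    s2 <- model$widths[2, g$q_set[r]]
    logw[, r] <- -((x1 - c1)^2) / (2 * s1^2) - ((x2 - c2)^2) / (2 * s2^2)
  }
  m <- apply(logw, 1, max)
  w <- exp(logw - m)
  w / rowSums(w)
}

# Per-rule first-order consequent outputs p_r(x) = a_r x1 + b_r x2 + d_r.
rule_outputs <- function(model, x1, x2) {
  cbind(x1, x2, 1) %*% t(model$consequents)
}

#' Evaluate an ANFIS model
#'
#' Forward pass: Gaussian memberships, product t-norm firing strengths,
#' normalization, and the weighted sum of the four first-order rule outputs.
#'
#' @param model An `anfis` object.
#' @param x_eeg,x_q Numeric vectors of input scores (recycled to a common
#'   length).
#'
#' @return Numeric vector of fused scores.
#' @export
anfis_forward <- function(model, x_eeg, x_q) {
  n <- max(length(x_eeg), length(x_q))
  x1 <- rep_len(x_eeg, n)
  x2 <- rep_len(x_q, n)
  if (!all(is.finite(x1)) || !all(is.finite(x2))) {
    stop_invalid("Inputs must be finite.", "trustfuse_invalid_argument")
  }
  wbar <- firing_strengths(model, x1, x2)
  rowSums(wbar * rule_outputs(model, x1, x2))
}

#' @export
predict.anfis <- function(object, newdata, ...) {
  xc <- attr(object, "config")$x_cols %||% c("eeg", "questionnaire")
  anfis_forward(object, newdata[[xc[1]]], newdata[[xc[2]]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Least-squares estimation of the 12 consequent coefficients with the
# premise frozen: ordinary least squares on the wbar-weighted design matrix,
# with a tiny ridge fallback if the system is singular.
lse_consequents <- function(wbar, x1, x2, y, ridge = 1e-8) {
  design <- do.call(cbind, lapply(1:4, function(r) {
    cbind(wbar[, r] * x1, wbar[, r] * x2, wbar[, r])
  }))
  fit <- tryCatch(qr.coef(qr(design), y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) {
    warning("Singular consequent system; falling back to ridge regression.")
    a <- crossprod(design) + diag(ridge, 12)
    fit <- solve(a, crossprod(design, y))
  }
  matrix(fit, 4, 3, byrow = TRUE, dimnames = list(NULL, c("a", "b", "d")))
}

# Analytic gradient of 0.5 * MSE with respect to premise centers/widths.
premise_gradient <- function(model, x1, x2, y) {
  wbar <- firing_strengths(model, x1, x2)
  p <- rule_outputs(model, x1, x2)
  yhat <- rowSums(wbar * p)
  e <- yhat - y
  n <- length(y)
  gc <- matrix(0, 2, 2, dimnames = dimnames(model$centers))
  gs <- gc
  g <- model$rules
  # d yhat / d logw_r = wbar_r * (p_r - yhat)
  dl <- wbar * (p - yhat)
  xs <- list(x1, x2)
  sets <- list(g$eeg_set, g$q_set)
  for (i in 1:2) {
    for (s in c("Low", "High")) {
      rs <- which(sets[[i]] == s)
      contrib <- rowSums(dl[, rs, drop = FALSE])
      c0 <- model$centers[i, s]
      s0 <- model$widths[i, s]
      gc[i, s] <- mean(e * contrib * (xs[[i]] - c0) / s0^2)
      gs[i, s] <- mean(e * contrib * (xs[[i]] - c0)^2 / s0^3)
    }
  }
  list(centers = gc, widths = gs, rmse = sqrt(mean(e^2)))
}

#' Fit an ANFIS model by hybrid learning
#'
#' Each epoch performs (i) exact least-squares estimation of the 12
#' consequent coefficients with the premise frozen, then (ii) one full-batch
#' gradient-descent step on the Gaussian centers and widths against squared
#' error. The returned model carries the parameters with the lowest training
#' RMSE observed across epochs, plus a per-epoch RMSE trace.
#'
#' @inheritParams anfis_init
#' @param epochs Number of hybrid epochs.
#' @param lr Gradient step size for the premise update.
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#'
#' @return An `anfis` object with attributes `trace` (tibble `epoch`,
#'   `rmse`) and `config`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   eeg = runif(30, 1, 10), questionnaire = runif(30, 1, 10)
#' )
#' d$behavior <- 0.5 * d$eeg + 0.5 * d$questionnaire
#' fit <- anfis_fit(d, epochs = 20)
#' glance(fit)
anfis_fit <- function(data, x_cols = c("eeg", "questionnaire"),
                      y_col = "behavior", epochs = 100, lr = 0.01, seed = 1) {
  if (nrow(data) < 12L) {
    stop_invalid("Need >= 12 training triples (one per consequent coefficient).", "trustfuse_invalid_argument")
  }
  model <- anfis_init(data, x_cols = x_cols, y_col = y_col)
  x1 <- data[[x_cols[1]]]
  x2 <- data[[x_cols[2]]]
  y <- data[[y_col]]
  best <- NULL
  best_rmse <- Inf
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    wbar <- firing_strengths(model, x1, x2)
    model$consequents <- lse_consequents(wbar, x1, x2, y)
    yhat <- rowSums(wbar * rule_outputs(model, x1, x2))
    rmse <- sqrt(mean((yhat - y)^2))
    trace[ep] <- rmse
    if (rmse < best_rmse) {
      best_rmse <- rmse
      best <- model[c("centers", "widths", "consequents")]
    }
    grad <- premise_gradient(model, x1, x2, y)
    model$centers <- model$centers - lr * grad$centers
    model$widths <- pmax(model$widths - lr * grad$widths, 1e-3)
  }
  new_anfis(best$centers, best$widths, best$consequents,
    trace = tibble::tibble(epoch = seq_len(epochs), rmse = trace),
    config = list(
      x_cols = x_cols, y_col = y_col, epochs = epochs,
      lr = lr, seed = seed, n = nrow(data), best_rmse = best_rmse
    )
  )
}

#' Leave-one-participant-out cross-validation of the ANFIS fusion
#'
#' Folds leave out all rows of one participant at a time (grouped, never
#' per-row, to avoid leaking within-participant structure), refit the model
#' on the remainder, and pool the held-out predictions. RMSE and
#' `R^2 = 1 - SSE/SST` are computed on the pooled predictions.
#'
#' @inheritParams anfis_fit
#' @param group_col Column defining the leave-out groups.
#'
#' @return A list: `rmse`, `r_squared`, `predictions` (tibble with the
#'   held-out `observed`/`predicted` per row), `n_folds`.
#' @export
anfis_loocv <- function(data, group_col = "participant",
                        x_cols = c("eeg", "questionnaire"),
                        y_col = "behavior", epochs = 100, lr = 0.01, seed = 1) {
  groups <- unique(data[[group_col]])
  if (length(groups) < 3L) {
    stop_invalid("Grouped LOOCV needs >= 3 participants.", "trustfuse_invalid_argument")
  }
  preds <- purrr::map_dfr(groups, function(g) {
    held <- data[[group_col]] == g
    fit <- anfis_fit(data[!held, , drop = FALSE],
      x_cols = x_cols, y_col = y_col,
      epochs = epochs, lr = lr, seed = seed
    )
    tibble::tibble(
      group = g,
      observed = data[[y_col]][held],
      predicted = predict(fit, data[held, , drop = FALSE])
    )
  })
  sse <- sum((preds$observed - preds$predicted)^2)
  sst <- sum((preds$observed - mean(preds$observed))^2)
  list(
    rmse = sqrt(mean((preds$observed - preds$predicted)^2)),
    r_squared = 1 - sse / sst,
    predictions = preds,
    n_folds = length(groups)
  )
}

#' Fused-score surface over the input grid
#'
#' Evaluates the fused trust score on a regular grid over both input axes,
#' the standard visualization of what the trained rule base has learned.
#'
#' @param model A fitted `anfis` object.
#' @param n Grid resolution per axis.
#' @param limits Length-2 numeric, common axis limits.
#'
#' @return A tibble with columns `eeg`, `questionnaire` and `fused`
#'   (`n * n` rows, EEG varying slowest).
#' @export
fusion_surface <- function(model, n = 21, limits = c(1, 10)) {
  ax <- seq(limits[1], limits[2], length.out = n)
  grid <- tidyr::expand_grid(eeg = ax, questionnaire = ax)
  grid$fused <- anfis_forward(model, grid$eeg, grid$questionnaire)
  grid
}

#' @export
print.anfis <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<anfis> first-order Takagi-Sugeno, 2 inputs x 2 Gaussian sets, 4 rules\n")
  if (!is.null(cfg$best_rmse)) {
    cat(sprintf(
      "  trained on %d triples, best training RMSE %.4f\n",
      cfg$n, cfg$best_rmse
    ))
  }
  invisible(x)
}

#' @describeIn anfis_fit Tidy the fitted parameters: one row per premise
#'   parameter (Gaussian center/width per input per set) and per consequent
#'   coefficient.
#' @param x An `anfis` object.
#' @param ... Unused.
#' @export
tidy.anfis <- function(x, ...) {
  prem <- tidyr::expand_grid(
    input = rownames(x$centers), set = colnames(x$centers)
  ) |>
    dplyr::mutate(
      component = "premise",
      center = as.vector(t(x$centers)),
      width = as.vector(t(x$widths))
    ) |>
    tidyr::pivot_longer(c("center", "width"), names_to = "term", values_to = "estimate") |>
    dplyr::select("component", "input", "set", "term", "estimate")
  cons <- tibble::as_tibble(x$consequents) |>
    dplyr::mutate(component = "consequent", rule = 1:4) |>
    tidyr::pivot_longer(c("a", "b", "d"), names_to = "term", values_to = "estimate") |>
    dplyr::transmute(
      component = .data$component,
      input = NA_character_, set = as.character(.data$rule),
      term = .data$term, estimate = .data$estimate
    )
  dplyr::bind_rows(prem, cons)
}

#' @describeIn anfis_fit One-row model summary (training RMSE, epochs, n).
#' @export
glance.anfis <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    rmse = cfg$best_rmse %||% NA_real_,
    epochs = cfg$epochs %||% NA_integer_,
    nobs = cfg$n %||% NA_integer_
  )
}

#' @describeIn anfis_fit Attach fused predictions to a data frame of input
#'   scores.
#' @param data Data frame with the model's input columns.
#' @export
augment.anfis <- function(x, data, ...) {
  data$.fused <- predict(x, data)
  tibble::as_tibble(data)
}
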