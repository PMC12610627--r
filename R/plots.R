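# ggplot2 views of the main result types.

#' @export
autoplot.trust_curve <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$t_s, y = .data$score, colour = .data$scenario)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$participant)) +
    ggplot2::labs(
      x = "time (s)", y = "trust score (1-10)",
      title = paste("Trust curve:", paste(unique(object$modality), collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.anfis <- function(object, n = 41, ...) {
  surf <- fusion_surface(object, n = n)
  ggplot2::ggplot(
    surf,
    ggplot2::aes(x = .data$eeg, y = .data$questionnaire, fill = .data$fused)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "fused score") +
    ggplot2::labs(
      x = "EEG trust score", y = "questionnaire trust score",
      title = "ANFIS fusion surface"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trust_agreement <- function(object, ...) {
  pct <- as.data.frame.table(object$confusion$row_pct, responseName = "pct")
  names(pct)[1:2] <- c("eeg", "questionnaire")
  ggplot2::ggplot(
    pct,
    ggplot2::aes(x = .data$questionnaire, y = .data$eeg, fill = .data$pct)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", name = "row %") +
    ggplot2::labs(
      x = "questionnaire level", y = "EEG level",
      title = "Trust-level classification agreement"
    ) +
    ggplot2::theme_minimal()
}

#' Training-trace plot for an ANFIS fit
#'
#' @param model A fitted `anfis` object carrying a training trace.
#' @return A ggplot of the per-epoch training RMSE.
#' @export
plot_training_trace <- function(model) {
  tr <- attr(model, "trace")
  if (is.null(tr)) {
    stop_invalid("Model carries no training trace.", "trustfuse_invalid_argument")
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training RMSE") +
    ggplot2::theme_minimal()
}
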