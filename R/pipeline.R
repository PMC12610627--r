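#' Run the full multimodal trust-assessment pipeline
#'
#' Chains every stage on a synthetic cohort: simulation, EEG trust scoring,
#' questionnaire scoring and alignment, behavioral scoring, ANFIS fusion
#' (full fit plus grouped leave-one-participant-out cross-validation), and
#' statistical validation. Optionally writes all artifacts to `out_dir`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; every random draw in every stage flows
#'   from it through named substreams.
#' @param epochs,lr ANFIS hybrid-learning schedule.
#' @param thresholds Low/High classification cut points on the score scale.
#' @param out_dir If non-`NULL`, artifacts (cohort files, trust-curve CSV,
#'   fusion-surface CSV, model JSON, validation JSON) are written here.
#' @param loocv Run grouped LOOCV (set `FALSE` to skip the slowest stage).
#' @param n_boot Bootstrap replicates for the kappa-difference tests.
#' @param verbose Emit one message per stage.
#'
#' @return A list of class `trust_report`: `score_table` (per-event aligned
#'   scores for all four modalities), `curves`, `model`, `loocv`,
#'   `validation`, `reliability`, `seed`, `config`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(cohort_config(n_participants = 4), seed = 1, loocv = FALSE)
#' rep$validation$correlation
#' }
run_pipeline <- function(config = cohort_config(), seed = 1,
                         epochs = 100, lr = 0.01,
                         thresholds = c(4.5, 7.0), out_dir = NULL,
                         loocv = TRUE, n_boot = 2000, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  say("stage=simulate seed=%d participants=%d", seed, config$n_participants)
  cohort <- simulate_cohort(config = config, seed = seed)

  say("stage=score-eeg recordings=%d", length(cohort$recordings))
  eeg_curves <- purrr::imap_dfr(cohort$recordings, function(rec, key) {
    ev <- dplyr::filter(
      cohort$events,
      .data$participant == attr(rec, "participant_id"),
      .data$scenario == attr(rec, "scenario_id")
    )
    compute_trust_curve(rec, ev)
  })

  say("stage=score-questionnaire responses=%d", nrow(cohort$questionnaire))
  q_scores <- score_questionnaire(cohort$questionnaire)
  q_curve <- align_to_events(q_scores, cohort$events, modality = "questionnaire")
  keyed_items <- apply_keying(item_matrix(cohort$questionnaire))
  alpha <- cronbach_alpha(keyed_items)

  say("stage=score-behavior codings=%d", nrow(cohort$behavior))
  b_scores <- score_behavior(cohort$behavior, norms = cohort$config$norms)
  b_curve <- align_to_events(b_scores, cohort$events, modality = "behavior")

  table <- eeg_curves |>
    dplyr::select("participant", "scenario", "event_id", "t_s", eeg = "score") |>
    dplyr::inner_join(
      dplyr::select(q_curve, "event_id", questionnaire = "score"),
      by = "event_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(b_curve, "event_id", behavior = "score"),
      by = "event_id"
    )

  say("stage=fuse n=%d epochs=%d", nrow(table), epochs)
  model <- anfis_fit(table,
    epochs = epochs, lr = lr,
    seed = derive_seed(seed, "anfis")
  )
  table$fused <- predict(model, table)
  cv <- if (loocv) {
    say("stage=loocv folds=%d", length(unique(table$participant)))
    anfis_loocv(table,
      epochs = epochs, lr = lr,
      seed = derive_seed(seed, "loocv")
    )
  } else {
    NULL
  }

  say("stage=validate")
  validation <- validate_modalities(table,
    thresholds = thresholds,
    n_boot = n_boot, seed = derive_seed(seed, "validate")
  )

  report <- structure(
    list(
      score_table = table,
      curves = list(
        eeg = eeg_curves, questionnaire = q_curve, behavior = b_curve
      ),
      model = model,
      loocv = cv,
      validation = validation,
      reliability = list(cronbach_alpha = alpha),
      seed = seed,
      config = config,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "trust_report"
  )
  if (!is.null(out_dir)) {
    say("stage=report out=%s", out_dir)
    write_report(report, cohort, out_dir)
  }
  report
}

write_report <- function(report, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  readr::write_csv(report$score_table, file.path(out_dir, "score_table.csv"))
  write_anfis(report$model, file.path(out_dir, "anfis_model.json"))
  readr::write_csv(
    fusion_surface(report$model),
    file.path(out_dir, "fusion_surface.csv")
  )
  v <- report$validation
  out <- list(
    seed = report$seed,
    reliability = report$reliability,
    dispersion = list(
      variances = v$dispersion$variances,
      kruskal = v$dispersion$kruskal,
      dunn = v$dispersion$dunn,
      anova = v$dispersion$anova
    ),
    correlation = v$correlation,
    kappa = v$agreement$kappa,
    kappa_differences = v$agreement$kappa_differences,
    confusion_counts = v$agreement$confusion$counts,
    confusion_row_pct = v$agreement$confusion$row_pct,
    loocv = if (!is.null(report$loocv)) {
      list(rmse = report$loocv$rmse, r_squared = report$loocv$r_squared)
    }
  )
  jsonlite::write_json(out, file.path(out_dir, "validation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.trust_report <- function(x, ...) {
  cat(sprintf(
    "<trust_report> seed %d, %d aligned events, %.1f s\n",
    x$seed, nrow(x$score_table), x$elapsed_s
  ))
  if (!is.null(x$loocv)) {
    cat(sprintf(
      " LOOCV: RMSE %.3f, R^2 %.3f\n",
      x$loocv$rmse, x$loocv$r_squared
    ))
  }
  print(x$validation)
  invisible(x)
}
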