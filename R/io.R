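# Readers and writers for the package's plain-text interchange formats:
# EEG CSV (`time_s,eeg_uV`), events JSON, questionnaire CSV, behavior CSV,
# trust-curve CSV, ANFIS model JSON and the cohort manifest JSON.

#' Read a single-channel EEG recording from CSV
#'
#' Expects a `time_s,eeg_uV` header (UTF-8, "." decimal; LF or CRLF).
#' Malformed rows and non-monotone time stamps are reported with row
#' numbers.
#'
#' @param path CSV file path.
#' @param rest_end_s Resting-baseline end (seconds).
#' @param participant_id,scenario_id Identifiers for the recording.
#'
#' @return A `trustfuse_eeg` recording; the sampling rate is inferred from
#'   the median time step.
#' @export
read_recording <- function(path, rest_end_s = 10,
                           participant_id = NA_character_,
                           scenario_id = NA_character_) {
  df <- tryCatch(
    # readr warns when the expected columns are absent; that case is turned
    # into a structured parse error below
    suppressWarnings(readr::read_csv(path,
      col_types = readr::cols(
        time_s = readr::col_double(), eeg_uV = readr::col_double()
      ),
      progress = FALSE
    )),
    error = function(e) {
      stop_invalid(sprintf("Cannot parse '%s': %s", path, conditionMessage(e)), "trustfuse_parse_error")
    }
  )
  if (!all(c("time_s", "eeg_uV") %in% names(df)) || nrow(df) == 0) {
    stop_invalid(
      sprintf("'%s' must have non-empty columns time_s,eeg_uV.", path),
      "trustfuse_parse_error"
    )
  }
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop_invalid(
      sprintf(
        "Malformed rows in '%s': %s",
        path, paste(utils::head(probs$row, 5), collapse = ", ")
      ),
      "trustfuse_parse_error"
    )
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stop_invalid(
      sprintf(
        "Non-monotone time stamps in '%s' at row(s) %s.",
        path, paste(utils::head(which(dt <= 0) + 1L, 5), collapse = ", ")
      ),
      "trustfuse_parse_error"
    )
  }
  fs <- 1 / median(dt)
  eeg_recording(df,
    fs = round(fs, 6), rest_end_s = rest_end_s,
    participant_id = participant_id, scenario_id = scenario_id
  )
}

#' Write / read a trust curve as CSV
#'
#' Dialect: `participant,scenario,event_id,t_s,modality,score`. The numeric
#' round trip is lossless to full double precision.
#'
#' @param curve A `trust_curve` tibble.
#' @param path CSV file path.
#' @export
write_trust_curve <- function(curve, path) {
  readr::write_csv(
    curve[c("participant", "scenario", "event_id", "t_s", "modality", "score")],
    path
  )
  invisible(path)
}

#' @rdname write_trust_curve
#' @export
read_trust_curve <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      participant = readr::col_character(),
      scenario = readr::col_character(),
      event_id = readr::col_character(),
      t_s = readr::col_double(),
      modality = readr::col_character(),
      score = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(df) == 0) {
    stop_invalid(sprintf("'%s' contains no curve points.", path), "trustfuse_parse_error")
  }
  new_trust_curve(df)
}

#' Serialize / deserialize an ANFIS model as JSON
#'
#' @param model An `anfis` object.
#' @param path JSON file path.
#' @export
write_anfis <- function(model, path) {
  obj <- list(
    premise = list(
      inputs = rownames(model$centers),
      sets = colnames(model$centers),
      centers = model$centers,
      widths = model$widths
    ),
    consequents = model$consequents,
    rule_table = model$rules,
    training_config = attr(model, "config")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_anfis
#' @export
read_anfis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- matrix(unlist(obj$premise$centers), 2, 2,
    dimnames = list(obj$premise$inputs, obj$premise$sets)
  )
  widths <- matrix(unlist(obj$premise$widths), 2, 2,
    dimnames = list(obj$premise$inputs, obj$premise$sets)
  )
  consequents <- matrix(unlist(obj$consequents), 4, 3,
    dimnames = list(NULL, c("a", "b", "d"))
  )
  new_anfis(centers, widths, consequents, config = obj$training_config)
}

#' Write a synthetic cohort to disk
#'
#' Emits, under `dir`: one EEG CSV per participant x scenario
#' (`eeg_<participant>_<scenario>.csv`, header `time_s,eeg_uV`), an events
#' JSON (`events.json`), the questionnaire and behavior CSVs
#' (spec dialects `participant,event_id,item01..item12` and
#' `participant,event_id,adherence_pct,latency_s,reliance,interventions,
#' verifications`), the latent trajectories CSV, and a `manifest.json`
#' echoing the seed and generator configuration. Given the same cohort the
#' output is byte-identical.
#'
#' @param cohort A `trust_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$recordings)) {
    readr::write_csv(
      tibble::as_tibble(cohort$recordings[[key]]),
      file.path(dir, sprintf("eeg_%s.csv", key))
    )
  }
  jsonlite::write_json(
    cohort$events[c("event_id", "t_start_s", "label", "scenario")],
    file.path(dir, "events.json"),
    digits = NA, pretty = TRUE
  )
  readr::write_csv(
    cohort$questionnaire[c("participant", "event_id", item_cols())],
    file.path(dir, "questionnaire.csv")
  )
  readr::write_csv(
    cohort$behavior[c(
      "participant", "event_id", "adherence_pct", "latency_s",
      "reliance", "interventions", "verifications"
    )],
    file.path(dir, "behavior.csv")
  )
  readr::write_csv(cohort$latent, file.path(dir, "latent.csv"))
  manifest <- list(
    seed = cohort$seed,
    n_participants = cohort$config$n_participants,
    scenarios = cohort$config$scenarios,
    events_per_scenario = cohort$config$events_per_scenario,
    fs = cohort$config$fs, rest_s = cohort$config$rest_s,
    latent = cohort$config$latent,
    artifacts = unclass(cohort$config$artifacts),
    questionnaire = cohort$config$questionnaire,
    behavior = cohort$config$behavior,
    norms = cohort$config$norms
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read questionnaire / behavior CSVs in the package dialects
#'
#' @param path CSV file path.
#' @export
read_questionnaire <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      participant = readr::col_character(),
      event_id = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE
  )
  if (!all(item_cols() %in% names(df))) {
    stop_invalid(sprintf("'%s' lacks item01..item12 columns.", path), "trustfuse_parse_error")
  }
  df
}

#' @rdname read_questionnaire
#' @export
read_behavior <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      participant = readr::col_character(),
      event_id = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE
  )
}
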