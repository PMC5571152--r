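#' Column schema for paired-trial tables
#'
#' The canonical long format: one row per treatment-vs-control pair from one
#' study. Means are in the units of [response_vocab()]; replicate counts are
#' the plot replications behind each arm mean.
#'
#' @return A tibble with columns `column`, `type`, `description`.
#' @export
trial_schema <- function() {
  tibble(
    column = c("study_id", "venue", "option", "response",
               "mean_treatment", "mean_control",
               "n_treatment", "n_control", "season", "texture_group"),
    type = c("character", "character", "character", "character",
             "double", "double", "integer", "integer",
             "character", "character"),
    description = c(
      "opaque study identifier",
      "on-station or on-farm",
      "treatment tillage/CE option code (never the control)",
      "response variable name",
      "treatment-arm mean (response units), > 0",
      "control-arm mean (response units), > 0",
      "treatment replicates, >= 1",
      "control replicates, >= 1",
      "dry, wet or unknown",
      "soil texture group or unknown"
    )
  )
}

validate_trial_rows <- function(df) {
  opts <- tce_options()
  reasons <- list(
    tibble(field = "option",
           reason = "unknown option code",
           bad = !(df$option %in% opts$code)),
    tibble(field = "option",
           reason = "control option used as treatment",
           bad = df$option %in% opts$code[opts$is_control]),
    tibble(field = "mean_treatment",
           reason = "nonpositive treatment mean",
           bad = !is.finite(df$mean_treatment) | df$mean_treatment <= 0),
    tibble(field = "mean_control",
           reason = "nonpositive control mean",
           bad = !is.finite(df$mean_control) | df$mean_control <= 0),
    tibble(field = "n_treatment",
           reason = "missing or nonpositive treatment replicate count",
           bad = is.na(df$n_treatment) | df$n_treatment < 1),
    tibble(field = "n_control",
           reason = "missing or nonpositive control replicate count",
           bad = is.na(df$n_control) | df$n_control < 1),
    tibble(field = "venue",
           reason = "unknown venue",
           bad = !(df$venue %in% venue_levels())),
    tibble(field = "response",
           reason = "unknown response name",
           bad = !(df$response %in% response_vocab()$response)),
    tibble(field = "season",
           reason = "unknown season level",
           bad = !(df$season %in% season_levels())),
    tibble(field = "texture_group",
           reason = "unknown texture group",
           bad = !(df$texture_group %in% texture_levels()))
  )
  rej <- purrr::map_dfr(reasons, function(r) {
    idx <- which(r$bad)
    tibble(row = idx, field = r$field[rep(1L, length(idx))],
           reason = r$reason[rep(1L, length(idx))])
  })
  dplyr::arrange(rej, .data$row)
}

#' Read a paired-trial table from delimited text
#'
#' Reads a UTF-8 CSV with a header row matching [trial_schema()], validates
#' every row, and returns the accepted observations. Rows failing a validity
#' rule (nonpositive mean, missing or nonpositive replicate count, unknown
#' option/venue/response/moderator code) are rejected individually; a missing
#' column is a schema error.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated observations with a `"rejections"` attribute
#'   (tibble with columns `row`, `field`, `reason`; `row` indexes the input
#'   data rows). Retrieve it with [trial_rejections()].
#' @seealso [write_trials()], [validate_pairing()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      venue = readr::col_character(),
      option = readr::col_character(),
      response = readr::col_character(),
      mean_treatment = readr::col_double(),
      mean_control = readr::col_double(),
      n_treatment = readr::col_integer(),
      n_control = readr::col_integer(),
      season = readr::col_character(),
      texture_group = readr::col_character(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  check_columns(raw, trial_schema()$column, basename(path))
  as_trials(raw[trial_schema()$column])
}

#' Validate an in-memory paired-trial table
#'
#' Applies the same row-level rules as [read_trials()] to a data frame built
#' in code.
#'
#' @param df A data frame with the columns of [trial_schema()].
#' @return A tibble of accepted rows with a `"rejections"` attribute.
#' @export
as_trials <- function(df) {
  check_columns(df, trial_schema()$column, "trials")
  df <- as_tibble(df)
  rej <- validate_trial_rows(df)
  keep <- setdiff(seq_len(nrow(df)), rej$row)
  out <- df[keep, , drop = FALSE]
  attr(out, "rejections") <- rej
  out
}

#' @rdname read_trials
#' @param trials A trials tibble returned by [read_trials()] or [as_trials()].
#' @export
trial_rejections <- function(trials) {
  attr(trials, "rejections") %||% tibble(row = integer(), field = character(),
                                         reason = character())
}

#' Write a paired-trial table to delimited text
#'
#' Inverse of [read_trials()]: a table written here and re-read compares
#' equal field by field.
#'
#' @param trials A trials tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_columns(trials, trial_schema()$column, "trials")
  readr::write_csv(trials[trial_schema()$column], path, progress = FALSE)
  invisible(path)
}

#' Report pairing structure ahead of weight division
#'
#' Scans a validated trial table and reports, without mutating anything:
#' studies contributing zero usable pairs (possible when a `study_ids`
#' roster is supplied), and duplicated (study, option, response) tuples whose
#' multiplicity will divide the replicate weights downstream.
#'
#' @param trials A trials tibble.
#' @param study_ids Optional character vector of expected study ids.
#' @return A tibble with columns `kind` (`"empty_study"` or
#'   `"multiplicity"`), `study_id`, `option`, `response`, `m`; attribute
#'   `n_studies` carries the number of distinct studies seen. An empty
#'   corpus yields a zero-row report with `n_studies = 0`.
#' @export
validate_pairing <- function(trials, study_ids = NULL) {
  check_columns(trials, trial_schema()$column, "trials")
  seen <- unique(trials$study_id)
  empty <- setdiff(study_ids %||% character(), seen)
  dup <- trials |>
    dplyr::count(.data$study_id, .data$option, .data$response, name = "m") |>
    dplyr::filter(.data$m > 1L)
  report <- dplyr::bind_rows(
    tibble(kind = rep("empty_study", length(empty)), study_id = empty,
           option = NA_character_, response = NA_character_,
           m = NA_integer_),
    tibble(kind = rep("multiplicity", nrow(dup)), study_id = dup$study_id,
           option = dup$option, response = dup$response, m = dup$m)
  )
  if (nrow(report) == 0L) {
    report <- tibble(kind = character(), study_id = character(),
                     option = character(), response = character(),
                     m = integer())
  }
  attr(report, "n_studies") <- length(seen)
  report
}
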