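#' Log response ratio
#'
#' The effect-size metric: the natural log of the treatment mean over the
#' control mean, `ln(mean_treatment / mean_control)`. Dimensionless;
#' antisymmetric under swapping the arms.
#'
#' @param mean_treatment,mean_control Strictly positive means in the same
#'   units. Vectorized.
#' @return Numeric vector of log response ratios.
#' @examples
#' log_response_ratio(1.05, 1) # ~ 0.04879
#' @export
log_response_ratio <- function(mean_treatment, mean_control) {
  if (any(!is.finite(mean_treatment)) || any(mean_treatment <= 0) ||
      any(!is.finite(mean_control)) || any(mean_control <= 0)) {
    abort("means must be finite and strictly positive",
          class = "ricemeta_domain_error")
  }
  log(mean_treatment / mean_control)
}

#' Replicate-based effect-size weight
#'
#' When study variances are unreported, pairs are weighted by replication:
#' `n_t * n_c / (n_t + n_c)` — half the harmonic mean of the two replicate
#' counts. Symmetric in its arguments and bounded above by `min(n_t, n_c)`.
#'
#' @param n_treatment,n_control Replicate counts, `>= 1`. Vectorized.
#' @return Numeric vector of weights.
#' @examples
#' replicate_weight(4, 4) # 2
#' replicate_weight(3, 6) # 2
#' @export
replicate_weight <- function(n_treatment, n_control) {
  if (any(is.na(n_treatment)) || any(n_treatment < 1) ||
      any(is.na(n_control)) || any(n_control < 1)) {
    abort("replicate counts must be >= 1", class = "ricemeta_domain_error")
  }
  n_treatment * n_control / (n_treatment + n_control)
}

#' Convert between log response ratio and percent change
#'
#' Pooled effects are reported as the percent change relative to the control:
#' `(exp(lnR) - 1) * 100`. `percent_to_lnr()` is its exact inverse.
#'
#' @param lnR Numeric vector of log response ratios.
#' @param percent Numeric vector of percent changes (> -100).
#' @return Numeric vector.
#' @examples
#' percent_change(log(1.05)) # 5
#' percent_to_lnr(5)         # log(1.05)
#' @export
percent_change <- function(lnR) (exp(lnR) - 1) * 100

#' @rdname percent_change
#' @export
percent_to_lnr <- function(percent) log(1 + percent / 100)

#' Build effect records from paired observations
#'
#' Computes the log response ratio and replicate weight for every pair, then
#' applies within-study weight division: if a study contributes `m`
#' observations to the same analysis category, each of those records keeps
#' `weight = raw_weight / m`, capping any single study's pull on the pooled
#' mean. The analysis category is the combination of response, contrast
#' group label, and (optionally) one moderator level.
#'
#' Multiplicity is counted after category assignment, so a study may carry
#' different `m` in different moderator strata. When a moderator is used,
#' rows with level `"unknown"` are excluded and their count is recorded in
#' the `"n_unknown_excluded"` attribute.
#'
#' @param trials A validated trials tibble (see [read_trials()]).
#' @param scheme Contrast scheme passed to [assign_group_labels()].
#' @param moderator Optional stratifier: `NULL` or one of `"venue"`,
#'   `"season"`, `"texture_group"`.
#' @return A tibble of effect records: `study_id`, `response`, `group_label`,
#'   `moderator_level` (`"<none>"` when unstratified), `lnR`, `raw_weight`,
#'   `multiplicity`, `weight`.
#' @export
build_effect_records <- function(trials,
                                 scheme = c("none", "tillage_contrast",
                                            "establishment_contrast"),
                                 moderator = NULL) {
  scheme <- rlang::arg_match(scheme)
  check_columns(trials, trial_schema()$column, "trials")
  labelled <- assign_group_labels(trials, scheme)
  n_unknown <- 0L
  if (is.null(moderator)) {
    labelled$moderator_level <- "<none>"
  } else {
    moderator <- rlang::arg_match(moderator,
                                  c("venue", "season", "texture_group"))
    labelled$moderator_level <- labelled[[moderator]]
    unknown <- labelled$moderator_level == "unknown"
    n_unknown <- sum(unknown)
    if (n_unknown > 0L) {
      inform(sprintf("excluding %d row(s) with unknown %s from stratified analysis",
                     n_unknown, moderator))
      labelled <- labelled[!unknown, , drop = FALSE]
    }
  }
  out <- labelled |>
    dplyr::mutate(
      lnR = log_response_ratio(.data$mean_treatment, .data$mean_control),
      raw_weight = replicate_weight(.data$n_treatment, .data$n_control)
    ) |>
    dplyr::group_by(.data$study_id, .data$response, .data$group_label,
                    .data$moderator_level) |>
    dplyr::mutate(multiplicity = dplyr::n(),
                  weight = .data$raw_weight / .data$multiplicity) |>
    dplyr::ungroup() |>
    dplyr::select("study_id", "response", "group_label", "moderator_level",
                  "lnR", "raw_weight", "multiplicity", "weight")
  attr(out, "n_unknown_excluded") <- n_unknown
  out
}

#' Screen extreme effect sizes within each category
#'
#' Flags records lying more than `threshold_sd` standard deviations from the
#' weighted mean effect size of their category, in a single pass. The centre
#' is the weight-weighted mean of `lnR`; the dispersion is the unweighted
#' sample SD. Categories with fewer than two records, or with zero
#' dispersion, pass through unscreened (identical values cannot be
#' outliers); both cases are counted in the `"screen_log"` attribute.
#'
#' @param records Effect records from [build_effect_records()].
#' @param threshold_sd Positive removal threshold in SD units (default 3;
#'   `Inf` disables removal).
#' @return The input records with logical `kept` and numeric `z_distance`
#'   columns appended, plus attributes `"screen_stats"` (per-category centre,
#'   SD and removal count) and `"screen_log"` (character vector of notes).
#'   Downstream pooling uses only rows with `kept == TRUE`.
#' @export
screen_outliers <- function(records, threshold_sd = 3) {
  stopifnot(is.numeric(threshold_sd), length(threshold_sd) == 1L,
            threshold_sd > 0)
  check_columns(records, c("response", "group_label", "moderator_level",
                           "lnR", "weight"), "effect records")
  out <- records |>
    dplyr::group_by(.data$response, .data$group_label,
                    .data$moderator_level) |>
    dplyr::mutate(
      .wmean = wmean(.data$lnR, .data$weight),
      .sd = sd(.data$lnR),
      z_distance = dplyr::if_else(
        dplyr::n() >= 2L & .data$.sd > 0,
        abs(.data$lnR - .data$.wmean) / .data$.sd,
        0
      ),
      kept = .data$z_distance <= threshold_sd
    ) |>
    dplyr::ungroup()
  stats <- out |>
    dplyr::group_by(.data$response, .data$group_label,
                    .data$moderator_level) |>
    dplyr::summarise(k = dplyr::n(),
                     weighted_mean = .data$.wmean[1],
                     sd_lnR = .data$.sd[1],
                     n_removed = sum(!.data$kept),
                     .groups = "drop")
  log <- character()
  small <- stats$k < 2L
  flat <- !small & (is.na(stats$sd_lnR) | stats$sd_lnR == 0)
  if (any(small)) {
    log <- c(log, sprintf("%d categor(ies) with < 2 records passed through unscreened",
                          sum(small)))
  }
  if (any(flat)) {
    log <- c(log, sprintf("%d zero-dispersion categor(ies) passed through unscreened",
                          sum(flat)))
  }
  out <- dplyr::select(out, -".wmean", -".sd")
  attr(out, "screen_stats") <- stats
  attr(out, "screen_log") <- log
  out
}
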