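#' Assemble a run configuration
#'
#' Bundles everything a pipeline command needs, with the published defaults
#' wired in: 4999 bootstrap iterations, a 3-SD outlier screen, and alpha =
#' 0.05. Values from a YAML config file can be overridden by arguments
#' (precedence: arguments > file > defaults).
#'
#' @param input Path to a trials CSV (not needed for [cmd_simulate()]).
#' @param response Response to analyse.
#' @param moderator Optional stratifier (`"venue"`, `"season"`,
#'   `"texture_group"`).
#' @param scheme Contrast scheme, see [assign_group_labels()].
#' @param iterations Bootstrap iterations.
#' @param seed Root seed for all randomness in the run.
#' @param threshold_sd Outlier screen threshold.
#' @param alpha Significance level.
#' @param out_dir Output directory (created on demand).
#' @param preset Simulation preset name (`"paper"`) or `NULL`.
#' @param config_file Optional YAML file supplying any of the above.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, response = "grain_yield",
                       moderator = NULL, scheme = "none",
                       iterations = 4999L, seed = 1L, threshold_sd = 3,
                       alpha = 0.05, out_dir = "ricemeta-run",
                       preset = "paper", config_file = NULL) {
  supplied <- as.list(match.call())[-1]
  supplied$config_file <- NULL
  cfg <- list(input = input, response = response, moderator = moderator,
              scheme = scheme, iterations = as.integer(iterations),
              seed = as.integer(seed), threshold_sd = threshold_sd,
              alpha = alpha, out_dir = out_dir, preset = preset)
  if (!is.null(config_file)) {
    from_file <- yaml::read_yaml(config_file)
    for (nm in names(from_file)) {
      if (!(nm %in% names(supplied))) cfg[[nm]] <- from_file[[nm]]
    }
  }
  cfg$iterations <- as.integer(cfg$iterations)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  config$out_dir
}

#' Write a machine-readable run manifest
#'
#' Records the configuration echo, seed, package and R versions, and an MD5
#' checksum of the input file — enough to reproduce the run exactly.
#'
#' @param config A `"run_config"`.
#' @param command Name of the command being run.
#' @param extra Named list of extra fields to record.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(config, command, extra = list()) {
  dir <- ensure_out_dir(config)
  manifest <- c(
    list(command = command,
         package_version = as.character(utils::packageVersion("ricemeta")),
         r_version = R.version.string,
         input_md5 = if (!is.null(config$input) && file.exists(config$input)) {
           unname(tools::md5sum(config$input))
         } else {
           NA_character_
         }),
    lapply(unclass(config), function(x) x %||% "null"),
    extra
  )
  path <- file.path(dir, paste0(command, "_manifest.yaml"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Pipeline commands
#'
#' The four stages of a reproducible run, each writing its artifacts and a
#' manifest into `config$out_dir`:
#'
#' * `cmd_simulate()` generates a synthetic corpus from the named preset
#'   (currently `"paper"`, see [preset_paper_shape()]) and writes
#'   `trials.csv` plus the serialized ground truth `truth.yaml`.
#' * `cmd_meta()` runs [run_meta_analysis()] and writes `meta_summary.csv`,
#'   the run log, and an SVG forest-style figure when the graphics device
#'   supports it.
#' * `cmd_mixed()` runs [unpivot_to_arms()] + [fit_reml()] and writes LS
#'   means with letters, variance components, and the pairwise p table.
#' * `cmd_report()` composes the side-by-side table juxtaposing
#'   meta-analysis percent changes and mixed-model LS means per option
#'   (`report.csv`), running both tracks if needed.
#'
#' Screening decisions (rejected rows, removed outliers, degenerate
#' categories) are always written to `<command>_log.txt`.
#'
#' @param config A `"run_config"` from [run_config()].
#' @return The primary artifact, invisibly: the trials tibble
#'   (`cmd_simulate`), the `meta_summary` (`cmd_meta`), the `"reml_fit"`
#'   (`cmd_mixed`), or the report tibble (`cmd_report`).
#' @export
cmd_simulate <- function(config) {
  dir <- ensure_out_dir(config)
  truth <- switch(config$preset %||% "paper",
                  paper = preset_paper_shape(seed = config$seed),
                  abort(sprintf("unknown preset '%s'", config$preset)))
  corpus <- generate_corpus(truth, seed = config$seed)
  write_trials(corpus, file.path(dir, "trials.csv"))
  write_sim_truth(truth, file.path(dir, "truth.yaml"))
  write_run_manifest(config, "simulate",
                     list(n_pairs = nrow(corpus),
                          n_studies = length(unique(corpus$study_id))))
  invisible(corpus)
}

#' @rdname cmd_simulate
#' @export
cmd_meta <- function(config) {
  dir <- ensure_out_dir(config)
  trials <- read_trials(config$input)
  summary <- run_meta_analysis(
    trials, response = config$response, moderator = config$moderator,
    scheme = config$scheme, iterations = config$iterations,
    seed = config$seed, threshold_sd = config$threshold_sd,
    level = 1 - config$alpha
  )
  write_meta_summary(summary, file.path(dir, "meta_summary.csv"))
  writeLines(run_log(summary), file.path(dir, "meta_log.txt"))
  if (capabilities("cairo")) {
    grDevices::svg(file.path(dir, "meta_forest.svg"), width = 7, height = 4.5)
    print(ggplot2::autoplot(summary))
    grDevices::dev.off()
  }
  write_run_manifest(config, "meta")
  invisible(summary)
}

#' @rdname cmd_simulate
#' @export
cmd_mixed <- function(config) {
  dir <- ensure_out_dir(config)
  trials <- read_trials(config$input)
  arms <- unpivot_to_arms(
    dplyr::filter(trials, .data$response == config$response)
  )
  fit <- fit_reml(arms)
  write_mixed_fit(fit, file.path(dir, "mixed"), alpha = config$alpha)
  writeLines(fit$flags, file.path(dir, "mixed_log.txt"))
  write_run_manifest(config, "mixed")
  invisible(fit)
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(config) {
  dir <- ensure_out_dir(config)
  summary <- cmd_meta(config)
  fit <- cmd_mixed(config)
  lett <- compact_letter_display(pairwise_compare(fit), alpha = config$alpha)
  meta_side <- summary |>
    as_tibble() |>
    dplyr::filter(.data$moderator_level == "<none>") |>
    dplyr::transmute(option = .data$group_label, track = "meta_analysis",
                     k = .data$k,
                     estimate = .data$percent_change,
                     ci_low = .data$percent_ci_low,
                     ci_high = .data$percent_ci_high,
                     annotation = dplyr::if_else(.data$significant, "*", ""))
  ctrl_mean <- fit$ls_means$ls_mean[fit$ls_means$option == control_option()]
  mixed_side <- fit$ls_means |>
    dplyr::transmute(option = .data$option, track = "mixed_model",
                     k = .data$n_arms,
                     estimate = .data$ls_mean,
                     ci_low = .data$ls_mean - 1.96 * .data$se,
                     ci_high = .data$ls_mean + 1.96 * .data$se,
                     annotation = unname(lett[.data$option]))
  report <- dplyr::bind_rows(meta_side, mixed_side) |>
    dplyr::arrange(.data$option, .data$track)
  readr::write_csv(report, file.path(dir, "report.csv"), progress = FALSE)
  write_run_manifest(config, "report",
                     list(control_ls_mean = ctrl_mean))
  invisible(report)
}
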