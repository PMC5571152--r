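# shared fixture builders; every fixture is generated in code

# a single well-formed pair, with fields overridable
make_pair <- function(study_id = "s1", option = "CT-DSR(wet)",
                      response = "grain_yield",
                      mean_treatment = 5.2, mean_control = 5.0,
                      n_treatment = 4L, n_control = 4L,
                      venue = "on-station", season = "wet",
                      texture_group = "clayey_fine") {
  tibble::tibble(
    study_id = study_id, venue = venue, option = option,
    response = response, mean_treatment = mean_treatment,
    mean_control = mean_control, n_treatment = n_treatment,
    n_control = n_control, season = season, texture_group = texture_group
  )
}

# a random valid corpus of raw rows (not yet validated)
random_trials <- function(n = 40, seed = 1, n_studies = 8) {
  withr::with_seed(seed, {
    make_pair(
      study_id = sample(sprintf("s%02d", seq_len(n_studies)), n,
                        replace = TRUE),
      option = sample(treatment_options(), n, replace = TRUE),
      response = sample(c("grain_yield", "water_input"), n, replace = TRUE),
      mean_treatment = exp(rnorm(n, log(5), 0.3)),
      mean_control = exp(rnorm(n, log(5), 0.3)),
      n_treatment = sample(3:6, n, replace = TRUE),
      n_control = sample(3:6, n, replace = TRUE),
      venue = sample(venue_levels(), n, replace = TRUE),
      season = sample(c("dry", "wet"), n, replace = TRUE),
      texture_group = sample(setdiff(texture_levels(), "unknown"), n,
                             replace = TRUE)
    )
  })
}

# balanced complete arm-level design: every study observes every option once
balanced_arms <- function(n_studies = 12, sigma_study = 0.5,
                          sigma_resid = 0.3, effects = NULL, seed = 1,
                          response = "grain_yield") {
  opts <- tce_options()$code
  effects <- effects %||% stats::setNames(seq_along(opts) * 0.2, opts)
  withr::with_seed(seed, {
    grid <- expand.grid(study_id = sprintf("b%02d", seq_len(n_studies)),
                        option = opts, stringsAsFactors = FALSE)
    u <- stats::setNames(stats::rnorm(n_studies, 0, sigma_study),
                         unique(grid$study_id))
    tibble::tibble(
      study_id = grid$study_id, option = grid$option, response = response,
      value = 5 + effects[grid$option] + u[grid$study_id] +
        stats::rnorm(nrow(grid), 0, sigma_resid)
    )
  })
}
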