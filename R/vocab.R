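#' Tillage / crop-establishment option vocabulary
#'
#' The six practice codes compared in the pipeline: conventional wet tillage
#' (puddling) with manual transplanting, `CT-TPR(wet)`, is the control; the
#' five alternatives vary tillage intensity (conventional CT, reduced RT,
#' zero ZT) and crop establishment (transplanted TPR vs direct-seeded DSR,
#' under wet or dry land preparation).
#'
#' @return A tibble with one row per option: `code`, `tillage_class`
#'   (`CT`/`RT`/`ZT`), `establishment_class` (`TPR`/`DSR`), and `is_control`.
#' @examples
#' tce_options()
#' @export
tce_options <- function() {
  tibble(
    code = c("CT-TPR(wet)", "CT-DSR(wet)", "CT-DSR(dry)",
             "RT-UPTPR(wet)", "RT-DSR(dry)", "ZT-DSR(dry)"),
    tillage_class = c("CT", "CT", "CT", "RT", "RT", "ZT"),
    establishment_class = c("TPR", "DSR", "DSR", "TPR", "DSR", "DSR"),
    is_control = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' @rdname tce_options
#' @export
control_option <- function() {
  opts <- tce_options()
  opts$code[opts$is_control]
}

#' @rdname tce_options
#' @export
treatment_options <- function() {
  opts <- tce_options()
  opts$code[!opts$is_control]
}

#' Response-variable vocabulary
#'
#' The six performance parameters the pipeline analyses, with their units.
#'
#' @return A tibble with columns `response` and `unit`.
#' @export
response_vocab <- function() {
  tibble(
    response = c("grain_yield", "water_input", "ch4", "n2o",
                 "cost", "net_return"),
    unit = c("Mg/ha", "mm/ha", "kg C/ha", "kg N/ha",
             "USD/ha", "USD/ha")
  )
}

#' Moderator level vocabularies
#'
#' Permitted levels for the season and soil-texture moderators. `"unknown"`
#' is allowed on ingest but rows carrying it are excluded (with a logged
#' count) from moderator-stratified analyses.
#'
#' @return A character vector of levels.
#' @export
season_levels <- function() c("dry", "wet", "unknown")

#' @rdname season_levels
#' @export
texture_levels <- function() {
  c("clayey_fine", "loamy_mod_fine", "loamy_medium",
    "loamy_mod_coarse", "sandy_coarse", "unknown")
}

#' @rdname season_levels
#' @export
venue_levels <- function() c("on-station", "on-farm")

#' Assign contrast group labels to paired observations
#'
#' Relabels treatment options into the coarser contrast groups used for the
#' tillage-intensity and crop-establishment questions:
#'
#' * `tillage_contrast` (CT vs RT/ZT): `CT-DSR(wet)` and `CT-DSR(dry)` form
#'   the `CT` group; `RT-DSR(dry)` and `ZT-DSR(dry)` form the `RT/ZT` group;
#'   `RT-UPTPR(wet)` rows are excluded so establishment method is held at DSR.
#' * `establishment_contrast` (TPR vs DSR): the four DSR options form the
#'   `DSR` group; the `TPR` group is represented by `RT-UPTPR(wet)` rows,
#'   since control arms have log response ratio zero by construction and
#'   cannot contribute their own ratio records.
#' * `none`: each option keeps its own code.
#'
#' @param trials A tibble of paired observations (see [read_trials()]).
#' @param scheme One of `"none"`, `"tillage_contrast"`,
#'   `"establishment_contrast"`.
#' @return The input tibble, possibly with excluded rows dropped, with a
#'   `group_label` column appended.
#' @examples
#' tr <- tibble::tibble(
#'   study_id = "s1", venue = "on-station", option = "ZT-DSR(dry)",
#'   response = "grain_yield", mean_treatment = 5, mean_control = 5.2,
#'   n_treatment = 4L, n_control = 4L, season = "wet",
#'   texture_group = "clayey_fine"
#' )
#' assign_group_labels(tr, "tillage_contrast")$group_label
#' @export
assign_group_labels <- function(trials,
                                scheme = c("none", "tillage_contrast",
                                           "establishment_contrast")) {
  scheme <- rlang::arg_match(scheme)
  check_columns(trials, "option", "trials")
  out <- switch(
    scheme,
    none = dplyr::mutate(trials, group_label = .data$option),
    tillage_contrast = trials |>
      dplyr::filter(.data$option != "RT-UPTPR(wet)") |>
      dplyr::mutate(group_label = dplyr::case_match(
        .data$option,
        c("CT-DSR(wet)", "CT-DSR(dry)") ~ "CT",
        c("RT-DSR(dry)", "ZT-DSR(dry)") ~ "RT/ZT"
      )),
    establishment_contrast = dplyr::mutate(
      trials,
      group_label = dplyr::case_match(
        .data$option,
        "RT-UPTPR(wet)" ~ "TPR",
        c("CT-DSR(wet)", "CT-DSR(dry)", "RT-DSR(dry)", "ZT-DSR(dry)") ~ "DSR"
      )
    )
  )
  bad <- is.na(out$group_label)
  if (any(bad)) {
    abort(sprintf("option code(s) not covered by scheme '%s': %s", scheme,
                  paste(unique(out$option[bad]), collapse = ", ")))
  }
  out
}
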