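#' Unpivot paired observations to arm-level records
#'
#' The mixed model works on arm means, not ratios: each pair contributes its
#' treatment-arm mean, and each (study, response) context contributes one
#' control-arm record. When a study reports several pairs for the same
#' response, its control arm is the mean of the reported control means, so
#' no control arm is duplicated.
#'
#' @param trials A validated trials tibble.
#' @return A tibble of arms: `study_id`, `option` (control included),
#'   `response`, `value`.
#' @export
unpivot_to_arms <- function(trials) {
  check_columns(trials, trial_schema()$column, "trials")
  treat <- trials |>
    dplyr::transmute(study_id = .data$study_id, option = .data$option,
                     response = .data$response,
                     value = .data$mean_treatment)
  ctrl <- trials |>
    dplyr::group_by(.data$study_id, .data$response) |>
    dplyr::summarise(value = mean(.data$mean_control), .groups = "drop") |>
    dplyr::mutate(option = control_option(), .after = "study_id")
  dplyr::bind_rows(treat, ctrl) |>
    dplyr::arrange(.data$study_id, .data$response, .data$option)
}

#' Fit the study-random-effect mixed model
#'
#' The confirmatory analysis parallel to the ratio-based meta-analysis: for
#' one response on its original measurement scale,
#' `value = mu + option + study + error`, with tillage/CE option (control
#' included) as a fixed effect and study as a random intercept, fitted by
#' REML. Least-squares means are the model-adjusted option means (the fixed
#' cell means, averaged over the study effects); arms are unweighted.
#'
#' @param arms Arm records from [unpivot_to_arms()], restricted to one
#'   response.
#' @return An object of class `"reml_fit"`: a list with `ls_means` (tibble of
#'   option, ls_mean, se, n_arms), `sigma_sq_study`, `sigma_sq_resid`,
#'   `reml_loglik`, `df_residual` (N minus fixed-effect rank minus number of
#'   studies plus one, floored at 1), `vcov_ls` (covariance of the LS means),
#'   `n`, `n_studies`, `response`, and `flags` (e.g. options observed in a
#'   single arm, which get wide standard errors).
#' @seealso [pairwise_compare()], [compact_letter_display()]
#' @export
fit_reml <- function(arms) {
  check_columns(arms, c("study_id", "option", "response", "value"), "arms")
  resp <- unique(arms$response)
  if (length(resp) != 1L) {
    abort("arms must contain exactly one response; filter first")
  }
  if (length(unique(arms$option)) < 2L) abort("need >= 2 options to fit")
  if (length(unique(arms$study_id)) < 2L) abort("need >= 2 studies to fit")

  dat <- data.frame(
    value = arms$value,
    option = factor(arms$option),
    study_id = factor(arms$study_id)
  )
  flags <- character()
  singles <- names(which(table(dat$option) == 1L))
  if (length(singles) > 0L) {
    flags <- c(flags, sprintf("option(s) observed in a single arm (wide SE): %s",
                              paste(singles, collapse = ", ")))
    warn(flags[length(flags)])
  }
  # cell-means coding: fixed coefficients are the LS means directly
  # tight final trust radius: balanced designs then agree with the
  # closed-form ANOVA estimators to ~1e-9
  fit <- lme4::lmer(value ~ 0 + option + (1 | study_id), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(
                      optimizer = "bobyqa", calc.derivs = FALSE,
                      optCtrl = list(rhoend = 1e-10)
                    ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_sq_study <- vc$vcov[vc$grp == "study_id"]
  sigma_sq_resid <- sigma(fit)^2
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  lev <- levels(dat$option)
  names(beta) <- sub("^option", "", names(beta))
  dimnames(V) <- list(names(beta), names(beta))
  n <- nrow(dat)
  n_studies <- nlevels(dat$study_id)
  df_residual <- max(1L, n - length(beta) - n_studies + 1L)
  structure(list(
    ls_means = tibble(
      option = names(beta),
      ls_mean = unname(beta),
      se = unname(sqrt(diag(V))),
      n_arms = as.integer(table(dat$option)[names(beta)])
    ),
    sigma_sq_study = sigma_sq_study,
    sigma_sq_resid = sigma_sq_resid,
    reml_loglik = as.numeric(logLik(fit)),
    df_residual = df_residual,
    vcov_ls = V,
    n = n, n_studies = n_studies,
    response = resp, flags = flags,
    model = fit
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("Study-random-effect REML fit: %s (n = %d arms, %d studies)\n",
              x$response, x$n, x$n_studies))
  cat(sprintf("  sigma^2 study: %.6g   sigma^2 residual: %.6g   REML logLik: %.4f\n",
              x$sigma_sq_study, x$sigma_sq_resid, x$reml_loglik))
  print(x$ls_means)
  invisible(x)
}

#' All-pairwise comparisons of least-squares means
#'
#' For each option pair, a t-type statistic on the LS-mean difference with
#' its model-based standard error, referred to the fit's residual degrees of
#' freedom; two-sided p-values. No multiplicity adjustment is applied by
#' default, matching unadjusted p < 0.05 reporting; `adjust = "bonferroni"`
#' is available.
#'
#' @param fit A `"reml_fit"` object.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A symmetric matrix of p-values with unit diagonal, options as
#'   dimnames.
#' @export
pairwise_compare <- function(fit, adjust = c("none", "bonferroni")) {
  adjust <- rlang::arg_match(adjust)
  stopifnot(inherits(fit, "reml_fit"))
  m <- fit$ls_means$ls_mean
  V <- fit$vcov_ls
  p_names <- fit$ls_means$option
  q <- length(m)
  P <- matrix(1, q, q, dimnames = list(p_names, p_names))
  n_pairs <- q * (q - 1) / 2
  for (i in seq_len(q - 1)) {
    for (j in seq((i + 1), q)) {
      se_d <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
      tval <- (m[i] - m[j]) / se_d
      p <- 2 * pt(-abs(tval), df = fit$df_residual)
      if (adjust == "bonferroni") p <- min(1, p * n_pairs)
      P[i, j] <- P[j, i] <- p
    }
  }
  P
}

#' Compact letter display by insert-and-absorb
#'
#' Encodes an all-pairwise comparison matrix as per-option letter strings
#' suitable for unbalanced designs. The insert-and-absorb algorithm starts
#' from one letter column containing every option; for each significantly
#' different pair still sharing a column, the column is duplicated, one
#' member deleted from each copy, and columns contained in another column
#' are absorbed. The result satisfies both display conditions: no
#' significant pair shares a letter, and every non-significant pair shares
#' at least one.
#'
#' @param pairwise Symmetric p-value matrix with dimnames, e.g. from
#'   [pairwise_compare()].
#' @param alpha Significance level (default 0.05).
#' @return A named character vector of letter strings, one per option, in
#'   the matrix's row order.
#' @examples
#' p <- matrix(c(1, .8, .01, .8, 1, .02, .01, .02, 1), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' compact_letter_display(p)
#' @export
compact_letter_display <- function(pairwise, alpha = 0.05) {
  stopifnot(is.matrix(pairwise), nrow(pairwise) == ncol(pairwise))
  if (!isTRUE(all.equal(pairwise, t(pairwise), tolerance = 1e-12))) {
    abort("pairwise p-value matrix must be symmetric")
  }
  opts <- rownames(pairwise) %||% as.character(seq_len(nrow(pairwise)))
  cols <- list(opts)
  q <- length(opts)
  for (i in seq_len(q - 1)) {
    for (j in seq((i + 1), q)) {
      if (pairwise[i, j] >= alpha) next
      a <- opts[i]; b <- opts[j]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop duplicates, then any column contained in another
      key <- vapply(new_cols, function(col) paste(sort(col), collapse = "\r"),
                    character(1))
      new_cols <- new_cols[!duplicated(key)]
      absorbed <- vapply(seq_along(new_cols), function(u) {
        any(vapply(seq_along(new_cols), function(v) {
          v != u && all(new_cols[[u]] %in% new_cols[[v]])
        }, logical(1)))
      }, logical(1))
      cols <- new_cols[!absorbed]
    }
  }
  # deterministic order: by first member's position in opts
  first_pos <- vapply(cols, function(col) min(match(col, opts)), numeric(1))
  cols <- cols[order(first_pos)]
  alphabet <- c(letters, paste0(rep(letters, each = 26),
                                rep(letters, times = 26)))
  out <- setNames(rep("", q), opts)
  for (ci in seq_along(cols)) {
    for (o in cols[[ci]]) out[o] <- paste0(out[o], alphabet[ci])
  }
  out
}

#' Export a mixed-model fit to delimited text
#'
#' Writes the LS means (with letters at `alpha`), the variance-component
#' block, and the square pairwise p-value table as three CSV files sharing
#' `prefix`.
#'
#' @param fit A `"reml_fit"` object.
#' @param prefix Path prefix; files `<prefix>_lsmeans.csv`,
#'   `<prefix>_varcomp.csv`, `<prefix>_pairwise.csv` are written.
#' @param alpha Significance level for the letter display.
#' @return The three paths, invisibly.
#' @export
write_mixed_fit <- function(fit, prefix, alpha = 0.05) {
  stopifnot(inherits(fit, "reml_fit"))
  P <- pairwise_compare(fit)
  lett <- compact_letter_display(P, alpha = alpha)
  paths <- paste0(prefix, c("_lsmeans.csv", "_varcomp.csv", "_pairwise.csv"))
  readr::write_csv(dplyr::mutate(fit$ls_means, letters = unname(lett)),
                   paths[1], progress = FALSE)
  readr::write_csv(tibble(
    component = c("sigma_sq_study", "sigma_sq_resid", "reml_loglik",
                  "df_residual", "n_arms", "n_studies"),
    value = c(fit$sigma_sq_study, fit$sigma_sq_resid, fit$reml_loglik,
              fit$df_residual, fit$n, fit$n_studies)
  ), paths[2], progress = FALSE)
  readr::write_csv(dplyr::bind_cols(tibble(option = rownames(P)),
                                    as_tibble(P)),
                   paths[3], progress = FALSE)
  invisible(paths)
}
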