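#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a study-random-effect mixed-model fit
#'
#' One row per tillage/CE option: the least-squares mean, its standard
#' error, arm count, and the compact letter at `alpha`.
#'
#' @param x A `"reml_fit"` object.
#' @param alpha Significance level for the letter display.
#' @param ... Unused.
#' @return A tibble with columns `option`, `ls_mean`, `se`, `n_arms`,
#'   `letters`.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, alpha = 0.05, ...) {
  lett <- compact_letter_display(pairwise_compare(x), alpha = alpha)
  dplyr::mutate(x$ls_means, letters = unname(lett[x$ls_means$option]))
}

#' Glance at a study-random-effect mixed-model fit
#'
#' @param x A `"reml_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: sizes, variance components, REML log-likelihood
#'   and residual df.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(
    n_arms = x$n, n_studies = x$n_studies,
    n_options = nrow(x$ls_means),
    sigma_sq_study = x$sigma_sq_study,
    sigma_sq_resid = x$sigma_sq_resid,
    reml_loglik = x$reml_loglik,
    df_residual = x$df_residual
  )
}
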