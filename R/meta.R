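#' Pool one category of effect records
#'
#' Categorical random-effects pooling: within a category, study effects vary
#' randomly around the group mean. The between-study variance `tau_sq` is the
#' generalized DerSimonian-Laird moment estimator with the replicate weights
#' taken as working precisions,
#' `tau_sq = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' `Q = sum(w_i (lnR_i - weighted mean)^2)`, and the pooled effect is the
#' mean under adjusted weights `w*_i = 1 / (1/w_i + tau_sq)`. A single
#' record pools to itself with `tau_sq = 0`.
#'
#' @param lnR Numeric vector of log response ratios (one category).
#' @param weight Positive weights, same length.
#' @param tau_sq Optional fixed between-study variance; when supplied the
#'   moment estimation is skipped (`tau_sq = 0` gives the plain weighted
#'   mean).
#' @return A one-row tibble: `k`, `pooled_lnR`, `tau_sq`, `Q_within`.
#' @examples
#' pool_category(c(0.10, 0.00, -0.05), c(2, 2.5, 2))
#' @export
pool_category <- function(lnR, weight, tau_sq = NULL) {
  k <- length(lnR)
  if (k == 0L) abort("cannot pool an empty category")
  stopifnot(length(weight) == k, all(weight > 0), all(is.finite(lnR)))
  if (k == 1L) {
    return(tibble(k = 1L, pooled_lnR = lnR, tau_sq = tau_sq %||% 0,
                  Q_within = 0))
  }
  sw <- sum(weight)
  m_fixed <- sum(weight * lnR) / sw
  Q <- sum(weight * (lnR - m_fixed)^2)
  c2 <- sw - sum(weight^2) / sw
  if (is.null(tau_sq)) {
    tau_sq <- max(0, (Q - (k - 1)) / c2)
  } else {
    stopifnot(tau_sq >= 0)
  }
  w_adj <- 1 / (1 / weight + tau_sq)
  tibble(k = k, pooled_lnR = sum(w_adj * lnR) / sum(w_adj),
         tau_sq = tau_sq, Q_within = Q)
}

# pooled_lnR for B bootstrap resamples at once (columns of idx)
boot_pooled_lnr <- function(lnR, weight, idx) {
  k <- nrow(idx)
  B <- ncol(idx)
  L <- matrix(lnR[idx], k, B)
  W <- matrix(weight[idx], k, B)
  sw <- .colSums(W, k, B)
  m_fixed <- .colSums(W * L, k, B) / sw
  Q <- .colSums(W * (L - rep(m_fixed, each = k))^2, k, B)
  c2 <- sw - .colSums(W * W, k, B) / sw
  tau_sq <- pmax(0, (Q - (k - 1)) / c2)
  W_adj <- 1 / (1 / W + rep(tau_sq, each = k))
  .colSums(W_adj * L, k, B) / .colSums(W_adj, k, B)
}

#' Bootstrap confidence interval for a pooled effect
#'
#' Resamples the category's effect records with replacement (each record
#' carries its weight), re-runs the full pooling including `tau_sq`
#' re-estimation on every resample, and returns nominal 95% bounds from the
#' bootstrap distribution of the pooled effect. The default is the
#' bias-corrected percentile interval; `"percentile"` selects plain
#' percentile bounds. Percentile positions use linear interpolation between
#' order statistics, so identical `seed` and `iterations` give bit-identical
#' bounds. `unit = "study"` resamples whole studies instead of records
#' (block bootstrap).
#'
#' With fewer than two records the interval degenerates to the point
#' estimate and is flagged via the `"degenerate"` attribute. If the bootstrap
#' distribution is one-sided around the estimate (bias correction undefined),
#' plain percentile bounds are returned and noted in the `"note"` attribute.
#'
#' @param lnR,weight The category's effect records.
#' @param iterations Number of bootstrap resamples (default 4999).
#' @param seed Integer seed; the bootstrap draws all its randomness from it.
#' @param method `"bias_corrected"` (default) or `"percentile"`.
#' @param unit `"record"` (default) or `"study"`; the latter requires
#'   `study_id`.
#' @param study_id Study ids, required for `unit = "study"`.
#' @param level Nominal coverage (default 0.95).
#' @return Numeric vector `c(ci_low, ci_high)` on the lnR scale.
#' @export
bootstrap_ci <- function(lnR, weight, iterations = 4999, seed,
                         method = c("bias_corrected", "percentile"),
                         unit = c("record", "study"), study_id = NULL,
                         level = 0.95) {
  method <- rlang::arg_match(method)
  unit <- rlang::arg_match(unit)
  if (iterations < 1) abort("iterations must be >= 1")
  k <- length(lnR)
  theta <- pool_category(lnR, weight)$pooled_lnR
  if (k < 2L) {
    out <- c(theta, theta)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  idx <- withr::with_seed(seed, {
    if (unit == "record") {
      matrix(sample.int(k, k * iterations, replace = TRUE), k, iterations)
    } else {
      stopifnot(!is.null(study_id), length(study_id) == k)
      groups <- split(seq_len(k), study_id)
      s <- length(groups)
      draws <- matrix(sample.int(s, s * iterations, replace = TRUE),
                      s, iterations)
      # ragged blocks: column lengths vary, pad by sampling rows per column
      apply(draws, 2L, function(cols) {
        unlist(groups[cols], use.names = FALSE)
      }, simplify = FALSE)
    }
  })
  if (unit == "record") {
    t_star <- boot_pooled_lnr(lnR, weight, idx)
  } else {
    t_star <- vapply(idx, function(rows) {
      pool_category(lnR[rows], weight[rows])$pooled_lnR
    }, numeric(1))
  }
  alpha <- (1 - level) / 2
  if (max(t_star) == min(t_star)) {
    return(c(t_star[1], t_star[1]))
  }
  probs <- c(alpha, 1 - alpha)
  note <- NULL
  if (method == "bias_corrected") {
    prop_below <- mean(t_star < theta)
    if (prop_below > 0 && prop_below < 1) {
      z0 <- qnorm(prop_below)
      probs <- pnorm(2 * z0 + qnorm(c(alpha, 1 - alpha)))
    } else {
      note <- "bias correction undefined (one-sided bootstrap distribution); plain percentile bounds used"
    }
  }
  out <- unname(quantile(t_star, probs, type = 7, names = FALSE))
  if (!is.null(note)) attr(out, "note") <- note
  out
}

#' Compare two category summaries by confidence-interval overlap
#'
#' Two categories are judged `"different"` exactly when their 95% intervals
#' are disjoint, mirroring the rule that a single effect is significant when
#' its interval excludes zero. Symmetric in its arguments.
#'
#' @param a,b One-row category summaries from [run_meta_analysis()] (or any
#'   rows carrying `response`, `ci_low`, `ci_high`).
#' @return `"different"` or `"not different"`.
#' @export
compare_categories <- function(a, b) {
  check_columns(a, c("response", "ci_low", "ci_high"), "summary a")
  check_columns(b, c("response", "ci_low", "ci_high"), "summary b")
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (!identical(a$response, b$response)) {
    abort("summaries compare different responses",
          class = "ricemeta_domain_error")
  }
  disjoint <- a$ci_high < b$ci_low || b$ci_high < a$ci_low
  if (disjoint) "different" else "not different"
}

#' Run the categorical meta-analysis pipeline
#'
#' Drives the full chain for one response: effect sizes and replicate
#' weights, within-study weight division, the SD-based outlier screen,
#' random-effects pooling per category, bootstrap confidence intervals, and
#' back-transformation to percent change. One summary row is emitted per
#' category (contrast group x optional moderator level); a category left
#' empty after screening is flagged `insufficient_data` rather than dropped.
#'
#' Each category's bootstrap uses a child seed derived from `seed` and the
#' category label via [derive_seed()], so results do not depend on category
#' order. Identical data, plan and seed give identical output.
#'
#' @param trials A validated trials tibble.
#' @param response Response to analyse (one of [response_vocab()]).
#' @param moderator Optional stratifier (`"venue"`, `"season"`,
#'   `"texture_group"`).
#' @param scheme Contrast scheme, see [assign_group_labels()].
#' @param iterations Bootstrap iterations (default 4999).
#' @param seed Root seed for the run.
#' @param threshold_sd Outlier screen threshold (default 3).
#' @param ci_method Passed to [bootstrap_ci()].
#' @param level Nominal CI coverage (default 0.95).
#' @return A tibble of class `"meta_summary"`, one row per category:
#'   `response`, `group_label`, `moderator_level`, `k`, `pooled_lnR`,
#'   `tau_sq`, `ci_low`, `ci_high`, `percent_change`, `percent_ci_low`,
#'   `percent_ci_high`, `significant`, `n_outliers_removed`,
#'   `insufficient_data`, `iterations`, `seed` (the child seed). The
#'   `"run_log"` attribute records exclusions, removals and degenerate
#'   categories.
#' @export
run_meta_analysis <- function(trials, response,
                              moderator = NULL,
                              scheme = c("none", "tillage_contrast",
                                         "establishment_contrast"),
                              iterations = 4999, seed = 1L,
                              threshold_sd = 3,
                              ci_method = c("bias_corrected", "percentile"),
                              level = 0.95) {
  scheme <- rlang::arg_match(scheme)
  ci_method <- rlang::arg_match(ci_method)
  response <- rlang::arg_match(response, response_vocab()$response)
  log <- character()
  rej <- trial_rejections(trials)
  if (nrow(rej) > 0L) {
    log <- c(log, sprintf("%d row(s) rejected on ingest", nrow(rej)))
  }
  sub <- dplyr::filter(trials, .data$response == !!response)
  if (nrow(sub) == 0L) abort(sprintf("no observations for response '%s'", response))

  records <- withCallingHandlers(
    build_effect_records(sub, scheme = scheme, moderator = moderator),
    message = function(m) {
      log <<- c(log, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  screened <- screen_outliers(records, threshold_sd = threshold_sd)
  log <- c(log, attr(screened, "screen_log"))
  n_removed_total <- sum(!screened$kept)
  if (n_removed_total > 0L) {
    log <- c(log, sprintf("%d outlier record(s) removed at %g SD",
                          n_removed_total, threshold_sd))
  }

  removed_per_cat <- screened |>
    dplyr::group_by(.data$response, .data$group_label,
                    .data$moderator_level) |>
    dplyr::summarise(n_outliers_removed = sum(!.data$kept), .groups = "drop")

  kept <- dplyr::filter(screened, .data$kept)
  cats <- dplyr::distinct(screened, .data$response, .data$group_label,
                          .data$moderator_level)
  out <- purrr::pmap_dfr(cats, function(response, group_label,
                                        moderator_level) {
    rec <- dplyr::filter(kept,
                         .data$response == !!response,
                         .data$group_label == !!group_label,
                         .data$moderator_level == !!moderator_level)
    key <- paste(response, group_label, moderator_level, sep = "|")
    child <- derive_seed(seed, key)
    if (nrow(rec) == 0L) {
      log <<- c(log, sprintf("category %s empty after screening", key))
      return(tibble(
        response = response, group_label = group_label,
        moderator_level = moderator_level, k = 0L,
        pooled_lnR = NA_real_, tau_sq = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        percent_change = NA_real_, percent_ci_low = NA_real_,
        percent_ci_high = NA_real_, significant = NA,
        insufficient_data = TRUE, iterations = iterations, seed = child
      ))
    }
    pool <- pool_category(rec$lnR, rec$weight)
    ci <- bootstrap_ci(rec$lnR, rec$weight, iterations = iterations,
                       seed = child, method = ci_method, level = level)
    if (isTRUE(attr(ci, "degenerate"))) {
      log <<- c(log, sprintf("category %s has a single record; degenerate CI", key))
    }
    if (!is.null(attr(ci, "note"))) {
      log <<- c(log, sprintf("category %s: %s", key, attr(ci, "note")))
    }
    tibble(
      response = response, group_label = group_label,
      moderator_level = moderator_level, k = pool$k,
      pooled_lnR = pool$pooled_lnR, tau_sq = pool$tau_sq,
      ci_low = ci[1], ci_high = ci[2],
      percent_change = percent_change(pool$pooled_lnR),
      percent_ci_low = percent_change(ci[1]),
      percent_ci_high = percent_change(ci[2]),
      significant = ci[1] > 0 | ci[2] < 0,
      insufficient_data = nrow(rec) < 2L,
      iterations = iterations, seed = child
    )
  })
  out <- out |>
    dplyr::left_join(removed_per_cat,
                     by = c("response", "group_label", "moderator_level")) |>
    dplyr::relocate("n_outliers_removed", .before = "insufficient_data") |>
    dplyr::arrange(.data$group_label, .data$moderator_level)
  attr(out, "run_log") <- log
  attr(out, "root_seed") <- seed
  class(out) <- c("meta_summary", class(out))
  out
}

#' @rdname run_meta_analysis
#' @param x A `meta_summary` tibble.
#' @export
run_log <- function(x) attr(x, "run_log") %||% character()

#' Write a meta-analysis summary to delimited text
#'
#' @param summary A `meta_summary` tibble from [run_meta_analysis()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_meta_summary <- function(summary, path) {
  readr::write_csv(as_tibble(summary), path, progress = FALSE)
  invisible(path)
}
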