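test_that("pooling matches direct weighted-average arithmetic", {
  res <- pool_category(c(0.10, 0.00, -0.05), c(2, 2.5, 2))
  expect_equal(res$tau_sq, 0) # Q below k - 1 here
  expect_equal(res$pooled_lnR, (0.10 * 2 - 0.05 * 2) / 6.5,
               tolerance = 1e-12)

  same <- pool_category(rep(0.3, 5), runif(5, 1, 3))
  expect_equal(same$pooled_lnR, 0.3)
  expect_equal(same$tau_sq, 0)
  expect_equal(same$Q_within, 0)

  lone <- pool_category(0.2, 1.5)
  expect_equal(lone$pooled_lnR, 0.2)
  expect_equal(lone$tau_sq, 0)
  expect_error(pool_category(numeric(), numeric()))
})

test_that("pooling invariants hold over random categories", {
  withr::with_seed(10, {
    for (i in 1:50) {
      k <- sample(2:40, 1)
      lnR <- rnorm(k, 0, 0.2)
      w <- runif(k, 0.5, 3)
      res <- pool_category(lnR, w)
      expect_gte(res$pooled_lnR, min(lnR))
      expect_lte(res$pooled_lnR, max(lnR))
      expect_gte(res$tau_sq, 0)
      if (res$Q_within <= k - 1) expect_equal(res$tau_sq, 0)
      # fixed-effect limit: tau_sq forced to 0 is the plain weighted mean
      expect_equal(pool_category(lnR, w, tau_sq = 0)$pooled_lnR,
                   sum(w * lnR) / sum(w), tolerance = 1e-12)
      # scaling all weights leaves the fixed-effect pool unchanged
      expect_equal(pool_category(lnR, w * 7.3, tau_sq = 0)$pooled_lnR,
                   pool_category(lnR, w, tau_sq = 0)$pooled_lnR,
                   tolerance = 1e-12)
    }
  })
})

test_that("moment estimator agrees with the DL route in metafor", {
  skip_if_not_installed("metafor")
  withr::with_seed(21, {
    for (i in 1:10) {
      k <- sample(5:30, 1)
      lnR <- rnorm(k, 0.05, 0.3)
      w <- runif(k, 0.5, 3)
      ours <- pool_category(lnR, w)
      ref <- metafor::rma(yi = lnR, vi = 1 / w, method = "DL")
      expect_equal(ours$tau_sq, unname(ref$tau2), tolerance = 1e-10)
      expect_equal(ours$pooled_lnR, unname(as.numeric(ref$b)),
                   tolerance = 1e-10)
    }
  })
})

test_that("adding a record above the pooled mean pulls it up (tau fixed)", {
  withr::with_seed(31, {
    lnR <- rnorm(8, 0, 0.1); w <- runif(8, 1, 2)
    base <- pool_category(lnR, w, tau_sq = 0.01)$pooled_lnR
    higher <- pool_category(c(lnR, base + 0.2), c(w, 1.4),
                            tau_sq = 0.01)$pooled_lnR
    expect_gt(higher, base)
  })
})

test_that("bootstrap CIs are seed-deterministic and degenerate correctly", {
  withr::with_seed(12, {
    lnR <- rnorm(20, 0.05, 0.2); w <- runif(20, 0.5, 3)
  })
  ci1 <- bootstrap_ci(lnR, w, iterations = 499, seed = 99)
  ci2 <- bootstrap_ci(lnR, w, iterations = 499, seed = 99)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(lnR, w, iterations = 499, seed = 100)
  expect_false(identical(ci1, ci3))

  flat <- bootstrap_ci(rep(0.2, 10), rep(2, 10), iterations = 199, seed = 1)
  expect_equal(unname(flat), c(0.2, 0.2))

  one <- bootstrap_ci(0.2, 2, iterations = 199, seed = 1)
  expect_true(isTRUE(attr(one, "degenerate")))
  expect_error(bootstrap_ci(lnR, w, iterations = 0, seed = 1))

  blk <- bootstrap_ci(lnR, w, iterations = 199, seed = 5, unit = "study",
                      study_id = rep(letters[1:5], each = 4))
  expect_length(blk, 2)
  expect_lte(blk[1], blk[2])
})

test_that("category comparison is the CI-disjointness rule, symmetric", {
  mk <- function(lo, hi) tibble::tibble(response = "grain_yield",
                                        ci_low = lo, ci_high = hi)
  expect_equal(compare_categories(mk(0.01, 0.03), mk(0.05, 0.08)),
               "different")
  expect_equal(compare_categories(mk(0.01, 0.06), mk(0.05, 0.08)),
               "not different")
  withr::with_seed(14, {
    for (i in 1:25) {
      a <- sort(runif(2, -1, 1)); b <- sort(runif(2, -1, 1))
      expect_equal(compare_categories(mk(a[1], a[2]), mk(b[1], b[2])),
                   compare_categories(mk(b[1], b[2]), mk(a[1], a[2])))
    }
  })
  other <- tibble::tibble(response = "water_input", ci_low = 0, ci_high = 1)
  expect_error(compare_categories(mk(0, 1), other),
               class = "ricemeta_domain_error")
})

test_that("the analysis run is deterministic and honors the contrast plan", {
  tr <- generate_corpus(sim_truth(n_studies = 25, pairs_per_study_mean = 4,
                                  seed = 3))
  s1 <- run_meta_analysis(tr, "grain_yield", iterations = 199, seed = 17)
  s2 <- run_meta_analysis(tr, "grain_yield", iterations = 199, seed = 17)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_meta_summary(s1, p1); write_meta_summary(s2, p2)
  expect_identical(readLines(p1), readLines(p2))

  till <- run_meta_analysis(tr, "grain_yield", scheme = "tillage_contrast",
                            moderator = "texture_group",
                            iterations = 99, seed = 17)
  expect_setequal(unique(till$group_label), c("CT", "RT/ZT"))
  # RT-UPTPR(wet) rows must not reach the tillage contrast
  n_excluded <- sum(tr$option == "RT-UPTPR(wet)")
  expect_equal(sum(till$k) + sum(till$n_outliers_removed),
               nrow(tr) - n_excluded)

  # significance flag is exactly "zero outside the interval"
  done <- dplyr::filter(tibble::as_tibble(s1), !insufficient_data)
  expect_equal(done$significant, done$ci_low > 0 | done$ci_high < 0)
  # percent bounds are the monotone transform of the lnR bounds
  expect_equal(done$percent_ci_low, (exp(done$ci_low) - 1) * 100)
  expect_equal(done$percent_ci_high, (exp(done$ci_high) - 1) * 100)
  expect_true(all(done$ci_low <= done$pooled_lnR + 1e-12 |
                    done$pooled_lnR <= done$ci_high + 1e-12))
})

test_that("category results do not depend on category iteration order", {
  tr <- generate_corpus(sim_truth(n_studies = 20, pairs_per_study_mean = 3,
                                  seed = 9))
  full <- run_meta_analysis(tr, "grain_yield", iterations = 199, seed = 4)
  # drop one option entirely; surviving categories must be unchanged
  sub <- as_trials(dplyr::filter(tr, option != "CT-DSR(wet)"))
  part <- run_meta_analysis(sub, "grain_yield", iterations = 199, seed = 4)
  joined <- dplyr::inner_join(
    tibble::as_tibble(full), tibble::as_tibble(part),
    by = c("response", "group_label", "moderator_level")
  )
  expect_gt(nrow(joined), 0)
  expect_equal(joined$ci_low.x, joined$ci_low.y)
  expect_equal(joined$ci_high.x, joined$ci_high.y)
})
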