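test_that("log response ratio matches analytic values and is antisymmetric", {
  expect_identical(log_response_ratio(5, 5), 0)
  expect_equal(log_response_ratio(1.05, 1), log(1.05))
  withr::with_seed(42, {
    a <- exp(rnorm(200)); b <- exp(rnorm(200))
    expect_equal(log_response_ratio(a, b), -log_response_ratio(b, a))
    # scale equivariance: common rescaling of both arms changes nothing
    c <- exp(rnorm(200))
    expect_equal(log_response_ratio(a * c, b * c), log_response_ratio(a, b))
  })
  expect_error(log_response_ratio(0, 1), class = "ricemeta_domain_error")
  expect_error(log_response_ratio(1, -2), class = "ricemeta_domain_error")
})

test_that("replicate weight is half the harmonic mean, symmetric and bounded", {
  expect_equal(replicate_weight(4, 4), 2)
  expect_equal(replicate_weight(3, 6), 2)
  withr::with_seed(7, {
    n1 <- sample(1:20, 100, replace = TRUE)
    n2 <- sample(1:20, 100, replace = TRUE)
    expect_equal(replicate_weight(n1, n1), n1 / 2)
    expect_equal(replicate_weight(n1, n2), replicate_weight(n2, n1))
    expect_true(all(replicate_weight(n1, n2) <= pmin(n1, n2)))
  })
  expect_error(replicate_weight(0, 3), class = "ricemeta_domain_error")
})

test_that("percent change is the exact back-transform of lnR", {
  expect_identical(percent_change(0), 0)
  expect_equal(percent_change(log(1.05)), 5)
  withr::with_seed(8, {
    p <- runif(500, -50, 100)
    expect_equal(percent_change(percent_to_lnr(p)), p)
  })
})

test_that("weight division follows per-study multiplicity within the category", {
  one <- as_trials(make_pair())
  rec1 <- build_effect_records(one)
  expect_equal(rec1$weight, 2)
  expect_equal(rec1$multiplicity, 1L)

  tri <- as_trials(make_pair(mean_treatment = c(5.1, 5.2, 5.3)))
  rec3 <- build_effect_records(tri)
  expect_equal(rec3$weight, rep(2 / 3, 3))
  expect_equal(rec3$multiplicity, rep(3L, 3))
  # division exactly undoes multiplicity when raw weights are equal
  expect_equal(sum(rec3$weight), rec3$raw_weight[1])

  # mixed corpus: brute-force recomputation by grouping and counting
  tr <- as_trials(random_trials(n = 80, seed = 5))
  rec <- build_effect_records(tr, scheme = "none", moderator = "season")
  key <- paste(rec$study_id, rec$response, rec$group_label,
               rec$moderator_level)
  m_oracle <- as.vector(table(key)[key])
  w_oracle <- replicate_weight(tr$n_treatment, tr$n_control) / m_oracle
  expect_equal(rec$multiplicity, m_oracle)
  expect_equal(rec$weight, w_oracle, tolerance = 1e-12)
  expect_equal(rec$lnR, log(tr$mean_treatment / tr$mean_control))
})

test_that("multiplicity is scoped to the analysis category", {
  # same study, same option/response, two seasons: joint analysis m = 2,
  # season-stratified analysis m = 1 in each stratum
  tr <- as_trials(make_pair(season = c("dry", "wet")))
  expect_equal(build_effect_records(tr)$multiplicity, c(2L, 2L))
  expect_equal(build_effect_records(tr, moderator = "season")$multiplicity,
               c(1L, 1L))
})

test_that("outlier screen removes exactly the extreme record", {
  base <- make_pair(study_id = sprintf("s%02d", 1:11),
                    mean_treatment = c(rep(5, 10), 5 * exp(5)),
                    mean_control = 5)
  rec <- build_effect_records(as_trials(base))
  screened <- screen_outliers(rec)
  expect_equal(sum(!screened$kept), 1L)
  expect_equal(screened$lnR[!screened$kept], 5)
  # hand oracle: weighted mean 5/11, unweighted SD, z of the extreme record
  z_hand <- abs(5 - 5 / 11) / sd(rec$lnR)
  expect_gt(z_hand, 3)
  expect_equal(max(screened$z_distance), z_hand)
  # conservation per category
  expect_equal(sum(screened$kept) + sum(!screened$kept), nrow(rec))
})

test_that("degenerate screens pass everything through", {
  flat <- build_effect_records(as_trials(
    make_pair(study_id = c("a", "b", "c"), mean_treatment = 5.5)
  ))
  expect_true(all(screen_outliers(flat)$kept))

  rec <- build_effect_records(as_trials(random_trials(n = 50, seed = 6)))
  expect_true(all(screen_outliers(rec, threshold_sd = Inf)$kept))

  single <- build_effect_records(as_trials(make_pair()))
  out <- screen_outliers(single)
  expect_true(all(out$kept))
  expect_true(any(grepl("< 2 records", attr(out, "screen_log"))))
})
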