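test_that("unpivoting yields one treatment arm per pair plus shared controls", {
  two_opts <- as_trials(make_pair(option = c("CT-DSR(wet)", "ZT-DSR(dry)")))
  arms <- unpivot_to_arms(two_opts)
  expect_equal(nrow(arms), 3L)
  expect_equal(sum(arms$option == control_option()), 1L)

  two_studies <- as_trials(make_pair(study_id = c("a", "b")))
  expect_equal(nrow(unpivot_to_arms(two_studies)), 4L)

  tr <- as_trials(random_trials(n = 70, seed = 13))
  arms <- unpivot_to_arms(tr)
  n_ctrl_oracle <- nrow(unique(tr[c("study_id", "response")]))
  expect_equal(nrow(arms), nrow(tr) + n_ctrl_oracle)
  expect_equal(sum(arms$option == control_option()), n_ctrl_oracle)
})

test_that("balanced-design variance components match closed-form ANOVA", {
  arms <- balanced_arms(n_studies = 15, sigma_study = 0.6,
                        sigma_resid = 0.25, seed = 3)
  fit <- fit_reml(arms)
  # expected-mean-squares oracle for the randomized complete block layout
  av <- anova(stats::aov(value ~ option + study_id,
                         data = transform(arms,
                                          option = factor(option),
                                          study_id = factor(study_id))))
  mse <- av["Residuals", "Mean Sq"]
  ms_study <- av["study_id", "Mean Sq"]
  t_opts <- length(unique(arms$option))
  expect_equal(fit$sigma_sq_resid, mse, tolerance = 1e-8)
  expect_equal(fit$sigma_sq_study, (ms_study - mse) / t_opts,
               tolerance = 1e-8)
  # with equal replication LS means are the raw option means
  raw <- tapply(arms$value, arms$option, mean)
  expect_equal(fit$ls_means$ls_mean,
               as.numeric(raw[fit$ls_means$option]), tolerance = 1e-8)
})

test_that("no between-study signal drives the study component to zero", {
  opts <- tce_options()$code
  arms <- tibble::tibble(
    study_id = rep(sprintf("s%d", 1:6), each = 6),
    option = rep(opts, times = 6),
    response = "grain_yield",
    value = rep(seq(4, 6.5, by = 0.5), times = 6)
  )
  fit <- suppressWarnings(fit_reml(arms))
  expect_lt(fit$sigma_sq_study, 1e-8)
})

test_that("LS means do not depend on option ordering or row order", {
  arms <- balanced_arms(n_studies = 10, seed = 5)
  fit_a <- fit_reml(arms)
  shuffled <- withr::with_seed(1, arms[sample.int(nrow(arms)), ])
  fit_b <- fit_reml(shuffled)
  expect_equal(fit_a$ls_means, fit_b$ls_means, tolerance = 1e-6)
  expect_equal(fit_a$sigma_sq_study, fit_b$sigma_sq_study,
               tolerance = 1e-6)
})

test_that("LS means agree with emmeans on unbalanced data", {
  skip_if_not_installed("emmeans")
  tr <- generate_corpus(sim_truth(n_studies = 30, pairs_per_study_mean = 4,
                                  seed = 21))
  fit <- fit_reml(unpivot_to_arms(tr))
  em <- as.data.frame(emmeans::emmeans(fit$model, "option",
                                       lmer.df = "asymptotic"))
  em$option <- sub("^option", "", as.character(em$option))
  ord <- match(fit$ls_means$option, em$option)
  expect_equal(fit$ls_means$ls_mean, em$emmean[ord], tolerance = 1e-6)
  expect_equal(fit$ls_means$se, em$SE[ord], tolerance = 1e-6)
})

test_that("REML optimum beats random variance-ratio probes", {
  tr <- generate_corpus(sim_truth(n_studies = 20, pairs_per_study_mean = 3,
                                  seed = 8))
  arms <- unpivot_to_arms(tr)
  fit <- fit_reml(arms)
  dat <- data.frame(value = arms$value, option = factor(arms$option),
                    study_id = factor(arms$study_id))
  devfun <- lme4::lmer(value ~ 0 + option + (1 | study_id), data = dat,
                       REML = TRUE, devFunOnly = TRUE)
  opt_theta <- lme4::getME(fit$model, "theta")
  probes <- withr::with_seed(2, exp(runif(50, log(1e-4), log(1e4))))
  expect_true(all(devfun(opt_theta) <= vapply(probes, devfun, numeric(1)) + 1e-6))
})

test_that("pairwise tests behave at the self, null and strong-shift limits", {
  arms <- balanced_arms(n_studies = 12, seed = 6)
  fit <- fit_reml(arms)
  P <- pairwise_compare(fit)
  expect_true(all(diag(P) == 1))
  expect_equal(P, t(P))
  expect_true(all(P >= 0 & P <= 1))

  # identical true effects: significant fraction near alpha
  withr::with_seed(30, {
    hits <- 0L; total <- 0L
    for (r in 1:40) {
      a <- balanced_arms(n_studies = 10, sigma_study = 0.4,
                         sigma_resid = 0.3,
                         effects = setNames(rep(0, 6), tce_options()$code),
                         seed = sample.int(1e6, 1))
      Pr <- pairwise_compare(fit_reml(a))
      hits <- hits + sum(Pr[upper.tri(Pr)] < 0.05)
      total <- total + sum(upper.tri(Pr))
    }
    expect_lt(abs(hits / total - 0.05), 0.04)
  })

  # one option shifted by 10 residual SDs is significant against all
  eff <- setNames(rep(0, 6), tce_options()$code)
  eff["ZT-DSR(dry)"] <- 3 # 10 x sigma_resid = 0.3
  strong <- balanced_arms(n_studies = 12, sigma_resid = 0.3,
                          effects = eff, seed = 11)
  Ps <- pairwise_compare(fit_reml(strong))
  expect_true(all(Ps["ZT-DSR(dry)", colnames(Ps) != "ZT-DSR(dry)"] < 0.05))

  # Bonferroni never decreases a p-value
  Pb <- pairwise_compare(fit, adjust = "bonferroni")
  expect_true(all(Pb >= P - 1e-15))
})

test_that("variance components are recovered on simulated corpora", {
  sigma_study <- 0.5; sigma_resid <- 0.3
  ests <- withr::with_seed(77, {
    t(vapply(1:60, function(r) {
      a <- balanced_arms(n_studies = 12, sigma_study = sigma_study,
                         sigma_resid = sigma_resid,
                         seed = sample.int(1e6, 1))
      f <- fit_reml(a)
      c(f$sigma_sq_study, f$sigma_sq_resid)
    }, numeric(2)))
  })
  for (j in 1:2) {
    truth <- c(sigma_study^2, sigma_resid^2)[j]
    se <- sd(ests[, j]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, j]) - truth), 3 * se + 0.01)
  }
})
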