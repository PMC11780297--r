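test_that("change scores subtract baseline and summarize with n-1 SD", {
  b <- data.frame(patient_id = c("a", "b", "c"), score = c(70, 70, 70))
  f <- data.frame(patient_id = c("a", "b", "c"), score = c(72, 74, 76))
  cs <- change_scores(b, f)
  expect_equal(cs$deltas$delta, c(2, 4, 6))
  expect_equal(cs$summary$mean_change, 4)
  expect_equal(cs$summary$sd_change, 2)
  # identical visits: all deltas zero, SD zero
  cs0 <- change_scores(b, b)
  expect_equal(cs0$summary$mean_change, 0)
  expect_equal(cs0$summary$sd_change, 0)
  # unmatched patients are excluded and reported
  f2 <- data.frame(patient_id = c("a", "b", "d"), score = c(78, 75, 99))
  cs2 <- change_scores(b, f2)
  expect_setequal(cs2$unmatched, c("c", "d"))
  expect_equal(nrow(cs2$deltas), 2)
  expect_equal(cs2$deltas$delta[cs2$deltas$patient_id == "a"], 8)
})

test_that("effect sizes match a construct-and-recompute oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    m1 <- stats::runif(1, -10, 10); m2 <- stats::runif(1, -10, 10)
    s1 <- stats::runif(1, 0.5, 20); s2 <- stats::runif(1, 0.5, 20)
    x <- sample_with_moments(n1, m1, s1)
    y <- sample_with_moments(n2, m2, s2)
    es <- cohen_d_from_summary(group_summary(n1, m1, s1),
                               group_summary(n2, m2, s2))
    expect_equal(es$d, brute_force_d(x, y), tolerance = 1e-8)
    # p value agrees with the pooled-variance t test on the raw samples
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(es$t_stat, unname(tt$statistic), tolerance = 1e-8)
    expect_equal(es$p_value, tt$p.value, tolerance = 1e-8)
    expect_equal(es$df, unname(tt$parameter))
  }
})

test_that("effect-size edge cases and antisymmetry hold", {
  g1 <- group_summary(10, 5, 3)
  g2 <- group_summary(12, 5, 7)
  expect_equal(cohen_d_from_summary(g1, g2)$d, 0)  # equal means
  fwd <- cohen_d_from_summary(group_summary(11, 6, 4),
                              group_summary(14, 2, 5))
  rev <- cohen_d_from_summary(group_summary(14, 2, 5),
                              group_summary(11, 6, 4))
  expect_equal(rev$d, -fwd$d)
  expect_equal(rev$ci_low, -fwd$ci_high)
  expect_equal(rev$ci_high, -fwd$ci_low)
  # zero pooled SD: d = 0 when means agree, an error otherwise
  expect_equal(cohen_d_from_summary(group_summary(5, 3, 0),
                                    group_summary(5, 3, 0))$d, 0)
  expect_error(cohen_d_from_summary(group_summary(5, 3, 0),
                                    group_summary(5, 4, 0)),
               "undefined")
  expect_error(two_sample_t(group_summary(5, 3, 0),
                            group_summary(5, 4, 0)), "undefined")
  id <- two_sample_t(group_summary(8, 1.5, 2), group_summary(8, 1.5, 2))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
})

test_that("CI width shrinks as both sample sizes grow", {
  widths <- vapply(c(5, 10, 20, 40, 80), function(n) {
    es <- cohen_d_from_summary(group_summary(n, 6, 15),
                               group_summary(n, 3, 12))
    es$ci_high - es$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # normal-quantile interval is strictly narrower than the t interval
  g1 <- group_summary(11, 6.36, 15.34); g2 <- group_summary(14, 3.75, 12.51)
  t_ci <- cohen_d_from_summary(g1, g2, ci_method = "t")
  z_ci <- cohen_d_from_summary(g1, g2, ci_method = "normal")
  expect_lt(z_ci$ci_high - z_ci$ci_low, t_ci$ci_high - t_ci$ci_low)
})

test_that("Rubin pooling matches the closed form", {
  p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$total_variance, 1 + (4 / 3) * 1)
  expect_equal(p$se, sqrt(7 / 3), tolerance = 1e-12)
  # identical estimates: between-variance vanishes
  p2 <- rubin_pool(rep(0.4, 10), seq(0.1, 1, length.out = 10))
  expect_equal(p2$between, 0)
  expect_equal(p2$total_variance, mean(seq(0.1, 1, length.out = 10)))
  # zero within-variance at m = 20: T = (21/20) B
  est <- stats::rnorm(20)
  p3 <- rubin_pool(est, rep(0, 20))
  expect_equal(p3$total_variance, (21 / 20) * stats::var(est))
  expect_error(rubin_pool(1, 1), "m >= 2")
  # m large: total variance approaches within + between (sample-variance
  # identity)
  set.seed(1)
  est <- stats::rnorm(1e4, 0, 2)
  p4 <- rubin_pool(est, rep(3, 1e4))
  expect_equal(p4$total_variance, 3 + stats::var(est), tolerance = 1e-3)
})

test_that("imputation reproduces complete data and deterministic fits", {
  df <- data.frame(x = 1:10, y = (1:10) * 2 + 1)
  # no missing cells: all m datasets equal the input
  imp <- mi_impute(df, outcome_cols = "y", predictor_cols = "x", m = 3,
                   seed = 1)
  for (dk in imp$datasets) expect_equal(dk, df)
  # single missing cell with an exact linear relation in complete cases:
  # the imputed value sits at the deterministic fit
  df2 <- df; df2$y[5] <- NA
  imp2 <- mi_impute(df2, outcome_cols = "y", predictor_cols = "x", m = 5,
                    seed = 2)
  vals <- vapply(imp2$datasets, function(dk) dk$y[5], numeric(1))
  expect_equal(vals, rep(11, 5), tolerance = 1e-3)
  # observed cells never change
  for (dk in imp2$datasets) expect_equal(dk$y[-5], df$y[-5])
  # over-missing columns are refused
  df3 <- df; df3$y[1:9] <- NA
  expect_error(mi_impute(df3, "y", "x", m = 2), "missingness limit")
  expect_error(mi_impute(data.frame(x = c(1, NA), y = c(1, 2)), "y", "x"),
               "predictor column")
})

test_that("PMM imputations are drawn from observed donor values", {
  set.seed(8)
  df <- data.frame(x = stats::rnorm(60))
  df$y <- 2 * df$x + stats::rnorm(60, 0, 0.5)
  miss <- sample(60, 12)
  obs_y <- df$y[-miss]
  df$y[miss] <- NA
  imp <- mi_impute(df, "y", "x", m = 4, method = "pmm", seed = 3)
  for (dk in imp$datasets) {
    expect_true(all(dk$y[miss] %in% obs_y))
  }
})

test_that("random-intercept LMM recovers a perfect line exactly", {
  d <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(patient_id = i, week = 1:8, y = 90 - 1 * (1:8))
  }))
  fit <- fit_random_intercept_lmm(d)
  expect_equal(fit$coefficients$estimate,
               c(90, -1), tolerance = 1e-8)
  expect_lt(fit$sigma_e2, 1e-8)
  expect_equal(fit$coefficients$df[2], nrow(d) - 6 - 1)
})

test_that("LMM agrees with an independent lme4 fit", {
  set.seed(31)
  d <- simulate_trajectories(10, 8, intercept = 92, slope = -0.95,
                             sigma_u = 10, sigma_e = 8)
  fit <- fit_random_intercept_lmm(d)
  ref <- lme4::lmer(y ~ week + (1 | patient_id), data = d, REML = TRUE)
  expect_equal(fit$coefficients$estimate,
               unname(lme4::fixef(ref)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma_u2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-4)
})

test_that("LMM falls back to OLS when the random intercept vanishes", {
  set.seed(12)
  d <- simulate_trajectories(8, 6, sigma_u = 5, sigma_e = 4)
  ols <- fit_random_intercept_lmm(d, random_intercept = FALSE)
  ref <- stats::lm(y ~ week, data = d)
  expect_equal(ols$coefficients$estimate, unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(ols$sigma_u2, 0)
  # one observation per subject: pinned to zero with a warning
  d1 <- d[!duplicated(d$patient_id), ]
  expect_warning(f1 <- fit_random_intercept_lmm(d1), "pinned to 0")
  expect_equal(f1$sigma_u2, 0)
})

test_that("feasibility metrics compute the screening funnel", {
  log <- data.frame(eligible = c(rep(TRUE, 10), rep(FALSE, 90)),
                    enrolled = c(rep(TRUE, 5), rep(FALSE, 95)),
                    randomized = c(rep(TRUE, 4), rep(FALSE, 96)),
                    completed_week4 = c(rep(TRUE, 4), rep(FALSE, 96)),
                    completed_week8 = c(rep(TRUE, 4), rep(FALSE, 96)))
  fm <- feasibility_metrics(log, months = 2)
  expect_equal(fm$recruitment_fraction_pct, 5)
  expect_equal(fm$retention_week4_pct, 100)
  expect_equal(fm$recruitment_rate_per_month, 2.5)
  expect_error(feasibility_metrics(log[0, ]), "empty")
  # 3 enrolled per month over 10 months
  log2 <- data.frame(enrolled = rep(TRUE, 30))
  expect_equal(feasibility_metrics(log2,
                                   months = 10)$recruitment_rate_per_month, 3)
})

test_that("results tables have one row per scale and follow-up visit", {
  set.seed(44)
  pats <- sprintf("P%02d", 1:20)
  arm <- rep(c("intervention", "control"), each = 10)
  scores <- expand.grid(patient_id = pats,
                        scale_id = c("s1", "s2"),
                        visit = c("baseline", "week4", "week8"),
                        stringsAsFactors = FALSE)
  scores$arm <- arm[match(scores$patient_id, pats)]
  scores$score <- stats::rnorm(nrow(scores), 70, 10)
  tab <- build_results_tables(scores)
  expect_equal(nrow(tab), 2 * 2)
  expect_true(all(c("d", "ci_low", "ci_high", "p_value") %in% names(tab)))
  expect_true(all(tab$ci_low <= tab$d & tab$d <= tab$ci_high))
  # null trial: no systematic effects
  expect_lt(max(abs(tab$d)), 1.5)
})
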