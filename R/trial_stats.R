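#' Group summary of a continuous outcome
#'
#' @param n Sample size (>= 2).
#' @param mean_change Group mean (of the change score, in the outcome's
#'   units).
#' @param sd_change Group standard deviation (n-1 denominator, >= 0).
#' @return A `group_summary` list.
#' @export
group_summary <- function(n, mean_change, sd_change) {
  stopifnot(n >= 2, sd_change >= 0)
  structure(list(n = as.integer(n), mean_change = mean_change,
                 sd_change = sd_change), class = "group_summary")
}

#' Per-patient change scores between two visits
#'
#' Matches patients between a baseline and a follow-up table and returns
#' follow-up minus baseline per patient, plus the group mean and SD
#' (n-1 denominator). Patients present in only one table are excluded and
#' reported.
#'
#' @param baseline,followup Data frames with columns `patient_id` and
#'   `score`.
#' @return List with `deltas` (data frame `patient_id`, `delta`),
#'   `summary` (a [group_summary()], `NULL` when fewer than 2 matched),
#'   and `unmatched` (character vector of dropped patient ids).
#' @export
change_scores <- function(baseline, followup) {
  baseline <- as.data.frame(baseline)
  followup <- as.data.frame(followup)
  shared <- intersect(baseline$patient_id, followup$patient_id)
  unmatched <- union(setdiff(baseline$patient_id, shared),
                     setdiff(followup$patient_id, shared))
  b <- baseline$score[match(shared, baseline$patient_id)]
  f <- followup$score[match(shared, followup$patient_id)]
  keep <- !is.na(b) & !is.na(f)
  deltas <- data.frame(patient_id = shared[keep], delta = f[keep] - b[keep],
                       stringsAsFactors = FALSE)
  summary <- if (nrow(deltas) >= 2L) {
    group_summary(nrow(deltas), mean(deltas$delta), stats::sd(deltas$delta))
  }
  list(deltas = deltas, summary = summary, unmatched = unmatched)
}

pooled_sd <- function(g1, g2) {
  df <- g1$n + g2$n - 2L
  sqrt(((g1$n - 1) * g1$sd_change^2 + (g2$n - 1) * g2$sd_change^2) / df)
}

#' Pooled-variance two-sample t test from group summaries
#'
#' Student's t with the pooled variance estimate and
#' `df = n1 + n2 - 2`; two-sided p value.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(g1, g2) {
  df <- g1$n + g2$n - 2L
  sp <- pooled_sd(g1, g2)
  se <- sp * sqrt(1 / g1$n + 1 / g2$n)
  if (se == 0) {
    if (g1$mean_change == g2$mean_change) {
      return(list(t = 0, df = df, p = 1))
    }
    stop("zero pooled SD with unequal means: t undefined")
  }
  t <- (g1$mean_change - g2$mean_change) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohen's d with a t-based confidence interval from group summaries
#'
#' The standardized mean difference `d = (m1 - m2) / s_p` with the pooled
#' SD `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, its large-
#' sample standard error
#' `se_d = sqrt((n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2)))`, and the
#' confidence interval `d +/- t_{1-alpha/2, n1+n2-2} * se_d`. The
#' t-quantile interval is the default because it is the convention in
#' small pilot trials; a normal-quantile variant is available. No
#' small-sample (Hedges) correction is applied. The accompanying test is
#' the pooled-variance two-sample t test on the means.
#'
#' @param g1,g2 [group_summary()] objects (first group minus second).
#' @param conf Confidence level (default 0.95).
#' @param ci_method `"t"` (default) or `"normal"`.
#' @return An `effect_size_result` list: `d`, `se_d`, `ci_low`, `ci_high`,
#'   `df`, `t_stat`, `p_value`, `n1`, `n2`.
#' @export
cohen_d_from_summary <- function(g1, g2, conf = 0.95,
                                 ci_method = c("t", "normal")) {
  ci_method <- match.arg(ci_method)
  df <- g1$n + g2$n - 2L
  sp <- pooled_sd(g1, g2)
  if (sp == 0) {
    if (g1$mean_change != g2$mean_change) {
      stop("zero pooled SD with unequal means: d undefined")
    }
    d <- 0
  } else {
    d <- (g1$mean_change - g2$mean_change) / sp
  }
  n1 <- g1$n; n2 <- g2$n
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  q <- switch(ci_method,
              t = stats::qt(1 - (1 - conf) / 2, df),
              normal = stats::qnorm(1 - (1 - conf) / 2))
  tt <- two_sample_t(g1, g2)
  structure(list(
    d = d, se_d = se_d, ci_low = d - q * se_d, ci_high = d + q * se_d,
    df = df, t_stat = tt$t, p_value = tt$p, n1 = n1, n2 = n2,
    conf = conf, ci_method = ci_method
  ), class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("Cohen d = %.2f (%d%% CI %.2f to %.2f), t(%d) = %.2f, p = %.3f\n",
              x$d, round(100 * x$conf), x$ci_low, x$ci_high, x$df,
              x$t_stat, x$p_value))
  invisible(x)
}

## ---- multiple imputation (chained equations, normal model / PMM) ----

# One Bayesian draw of a normal linear imputation model:
# sigma^2* ~ SSE / chisq(df), beta* ~ N(beta_hat, sigma^2* (X'X)^-1).
draw_norm_model <- function(X, y) {
  qrx <- qr(X)
  beta_hat <- qr.coef(qrx, y)
  beta_hat[is.na(beta_hat)] <- 0
  res <- y - X %*% beta_hat
  df <- max(length(y) - qrx$rank, 1L)
  # floor keeps the posterior draw proper when complete cases fit exactly
  sigma2 <- max(sum(res^2), 1e-10) / stats::rchisq(1, df)
  R <- qr.R(qrx)[seq_len(qrx$rank), seq_len(qrx$rank), drop = FALSE]
  keep <- qrx$pivot[seq_len(qrx$rank)]
  cov_free <- chol2inv(R)
  beta <- beta_hat
  beta[keep] <- beta_hat[keep] +
    drop(t(chol(cov_free * sigma2)) %*% stats::rnorm(length(keep)))
  list(beta = beta, sigma = sqrt(sigma2))
}

impute_column <- function(X, y, miss, method) {
  dm <- draw_norm_model(X[!miss, , drop = FALSE], y[!miss])
  pred_mis <- drop(X[miss, , drop = FALSE] %*% dm$beta)
  if (method == "norm") {
    return(pred_mis + stats::rnorm(sum(miss), 0, dm$sigma))
  }
  # predictive mean matching against observed donors
  pred_obs <- drop(X[!miss, , drop = FALSE] %*% dm$beta)
  y_obs <- y[!miss]
  vapply(pred_mis, function(p) {
    donors <- order(abs(pred_obs - p))[seq_len(min(5L, length(y_obs)))]
    y_obs[sample(donors, 1L)]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Fills missing cells in the outcome columns by iterating a Bayesian
#' normal linear imputation model over the incomplete columns, each
#' regressed on the complete predictor columns plus the other (currently
#' imputed) outcome columns. Repeating the procedure `m` times (20 in the
#' trial's analysis) yields `m` completed datasets whose observed cells
#' are identical and whose imputed cells vary with the posterior draws. A
#' predictive-mean-matching variant draws imputed values from the 5
#' observed donors with the closest model predictions.
#'
#' @param data Data frame; missingness is only allowed in `outcome_cols`.
#' @param outcome_cols Character vector of (possibly incomplete) numeric
#'   outcome columns.
#' @param predictor_cols Character vector of complete predictor columns
#'   (numeric or factor/character, expanded via `model.matrix`).
#' @param m Number of imputations (default 20).
#' @param maxit Chained-equation sweeps per imputation (default 5).
#' @param method `"norm"` (normal-model draws) or `"pmm"`.
#' @param seed Optional integer seed for reproducibility.
#' @param max_missing_frac Refuse columns missing more than this fraction
#'   (default 0.8).
#' @return An `imputation_set`: list with `datasets` (list of m completed
#'   data frames), `m`, `method`, `outcome_cols`, `predictor_cols`,
#'   `seed`.
#' @export
mi_impute <- function(data, outcome_cols, predictor_cols, m = 20L,
                      maxit = 5L, method = c("norm", "pmm"), seed = NULL,
                      max_missing_frac = 0.8) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  if (!is.null(seed)) set.seed(seed)
  for (p in predictor_cols) {
    if (anyNA(data[[p]])) stop("predictor column has missing values: ", p)
  }
  frac <- vapply(outcome_cols, function(cl) mean(is.na(data[[cl]])),
                 numeric(1))
  if (any(frac > max_missing_frac)) {
    stop("column(s) exceed the missingness limit: ",
         paste(outcome_cols[frac > max_missing_frac], collapse = ", "))
  }
  incomplete <- outcome_cols[frac > 0]
  miss_idx <- lapply(incomplete, function(cl) is.na(data[[cl]]))
  names(miss_idx) <- incomplete
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    dk <- data
    # initialize missing cells with random draws from the observed values
    for (cl in incomplete) {
      mi <- miss_idx[[cl]]
      dk[[cl]][mi] <- sample(dk[[cl]][!mi], sum(mi), replace = TRUE)
    }
    n_sweeps <- if (length(incomplete)) maxit else 0L
    for (it in seq_len(n_sweeps)) {
      for (cl in incomplete) {
        mi <- miss_idx[[cl]]
        rhs <- c(predictor_cols, setdiff(outcome_cols, cl))
        form <- stats::reformulate(if (length(rhs)) rhs else "1")
        X <- stats::model.matrix(form, dk)
        dk[[cl]][mi] <- impute_column(X, dk[[cl]], mi, method)
      }
    }
    datasets[[k]] <- dk
  }
  structure(list(datasets = datasets, m = m, method = method,
                 outcome_cols = outcome_cols,
                 predictor_cols = predictor_cols, seed = seed),
            class = "imputation_set")
}

#' Pool estimates across imputed datasets (Rubin's rules)
#'
#' The pooled estimate is the mean of the per-dataset estimates; the
#' total variance adds the mean within-imputation variance and
#' `(1 + 1/m)` times the between-imputation variance of the estimates.
#'
#' @param estimates Numeric vector of per-dataset estimates (length m >= 2).
#' @param variances Numeric vector of per-dataset squared standard errors.
#' @return List with `estimate`, `within`, `between`, `total_variance`,
#'   `se`, `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2L || length(variances) != m) {
    stop("need matched estimate/variance vectors of length m >= 2")
  }
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  list(estimate = qbar, within = w, between = b, total_variance = total,
       se = sqrt(total), m = m)
}

#' Random-intercept linear mixed model for weekly trajectories
#'
#' Fits `y ~ week` with a patient-level random intercept by REML (via
#' `nlme::lme`, the engine the trial's own analysis used), the standard
#' model for weekly adherence/activity trajectories with intrasubject
#' correlation. Wald t statistics use the within-subject denominator df
#' convention `N_obs - N_subjects - 1`. When every subject contributes a
#' single observation the random intercept is not identifiable and the
#' model degrades to ordinary least squares with the variance pinned to
#' zero (with a warning); `random_intercept = FALSE` forces that OLS fit.
#'
#' @param data Long data frame.
#' @param outcome,week,id Column names (default `"y"`, `"week"`,
#'   `"patient_id"`).
#' @param random_intercept Set `FALSE` to fit plain OLS (no random
#'   effect).
#' @return An `lmm_result` list: `coefficients` (data frame with
#'   `estimate`, `se`, `t`, `df`, `p` for intercept and slope),
#'   `sigma_u2` (random-intercept variance), `sigma_e2` (residual
#'   variance), `logLik` (REML), `n_obs`, `n_subjects`.
#' @export
fit_random_intercept_lmm <- function(data, outcome = "y", week = "week",
                                     id = "patient_id",
                                     random_intercept = TRUE) {
  data <- as.data.frame(data)
  data <- data[!is.na(data[[outcome]]) & !is.na(data[[week]]), ]
  d <- data.frame(y = data[[outcome]], week = data[[week]],
                  id = factor(data[[id]]))
  n_obs <- nrow(d)
  n_sub <- nlevels(d$id)
  if (n_obs < 3L) stop("need at least 3 observations")
  per_sub <- table(d$id)
  ols_fallback <- function(warn = NULL) {
    if (!is.null(warn)) warning(warn)
    fit <- stats::lm(y ~ week, data = d)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    df <- fit$df.residual
    tval <- est / se
    structure(list(
      coefficients = data.frame(
        term = c("intercept", "slope"), estimate = unname(est),
        se = unname(se), t = unname(tval), df = df,
        p = 2 * stats::pt(-abs(unname(tval)), df)),
      sigma_u2 = 0, sigma_e2 = summary(fit)$sigma^2,
      logLik = as.numeric(stats::logLik(fit)),
      n_obs = n_obs, n_subjects = n_sub, engine = "ols"
    ), class = "lmm_result")
  }
  if (!random_intercept) return(ols_fallback())
  if (all(per_sub == 1L)) {
    return(ols_fallback(
      "one observation per subject: random-intercept variance pinned to 0"))
  }
  fit <- nlme::lme(y ~ week, random = ~ 1 | id, data = d,
                   method = "REML")
  est <- nlme::fixef(fit)
  se <- sqrt(diag(fit$varFix))
  vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
  df <- n_obs - n_sub - 1L
  tval <- est / se
  structure(list(
    coefficients = data.frame(
      term = c("intercept", "slope"), estimate = unname(est),
      se = unname(se), t = unname(tval), df = df,
      p = 2 * stats::pt(-abs(unname(tval)), df)),
    sigma_u2 = vc[1L], sigma_e2 = vc[2L],
    logLik = as.numeric(stats::logLik(fit)),
    n_obs = n_obs, n_subjects = n_sub, engine = "lme"
  ), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s): %d obs, %d subjects\n",
              x$engine, x$n_obs, x$n_subjects))
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("sigma_u2 = %.3f, sigma_e2 = %.3f\n", x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' Recruitment and retention feasibility metrics
#'
#' @param log Data frame with one row per screened patient and logical
#'   columns `eligible`, `enrolled`, `randomized`, `completed_week4`,
#'   `completed_week8` (missing columns are treated as all-`FALSE`).
#' @param months Length of the recruitment period in months.
#' @return A `feasibility_metrics` list with counts, the recruitment
#'   fraction (percent enrolled of screened, 1 decimal place), retention
#'   percentages at each follow-up among randomized patients, and the
#'   monthly recruitment rate.
#' @export
feasibility_metrics <- function(log, months = NULL) {
  log <- as.data.frame(log)
  n_screened <- nrow(log)
  if (n_screened == 0L) stop("empty screening log")
  col <- function(name) {
    if (name %in% names(log)) log[[name]] %in% TRUE else rep(FALSE, n_screened)
  }
  n_eligible <- sum(col("eligible"))
  n_enrolled <- sum(col("enrolled"))
  n_randomized <- sum(col("randomized"))
  n_week4 <- sum(col("completed_week4"))
  n_week8 <- sum(col("completed_week8"))
  structure(list(
    n_screened = n_screened, n_eligible = n_eligible,
    n_enrolled = n_enrolled, n_randomized = n_randomized,
    n_completed_week4 = n_week4, n_completed_week8 = n_week8,
    recruitment_fraction_pct = round(100 * n_enrolled / n_screened, 1),
    retention_week4_pct = if (n_randomized) 100 * n_week4 / n_randomized,
    retention_week8_pct = if (n_randomized) 100 * n_week8 / n_randomized,
    recruitment_rate_per_month = if (!is.null(months)) n_enrolled / months
  ), class = "feasibility_metrics")
}

#' Build the trial's outcome tables
#'
#' For every scale and post-baseline visit, computes each arm's change
#' summary (intent-to-treat: every randomized patient in their assigned
#' arm), the pooled-SD Cohen's d with its confidence interval, and the
#' two-sample t test p value - the shape of a standard pilot-trial
#' results table. Effect sizes are reported as intervention minus
#' control. Rows where a visit is missing for all patients of a scale are
#' omitted with a warning.
#'
#' @param scores Long data frame: `patient_id`, `arm`, `scale_id`,
#'   `visit` (`"baseline"`, `"week4"`, `"week8"`), `score`.
#' @param arms Length-2 character vector, intervention arm first.
#' @param conf,ci_method Passed to [cohen_d_from_summary()].
#' @param digits Rounding applied to the d/CI columns (default 2, `NULL`
#'   for none).
#' @return Data frame with one row per (scale, visit).
#' @export
build_results_tables <- function(scores, arms = c("intervention", "control"),
                                 conf = 0.95, ci_method = "t", digits = 2) {
  scores <- as.data.frame(scores)
  visits <- intersect(c("week4", "week8"), unique(scores$visit))
  rows <- list()
  for (sc in unique(scores$scale_id)) {
    s <- scores[scores$scale_id == sc, ]
    base <- s[s$visit == "baseline", c("patient_id", "arm", "score")]
    for (v in visits) {
      fu <- s[s$visit == v, c("patient_id", "arm", "score")]
      gs <- lapply(arms, function(a) {
        change_scores(base[base$arm == a, ], fu[fu$arm == a, ])$summary
      })
      if (any(vapply(gs, is.null, logical(1)))) {
        warning(sprintf("scale %s, visit %s: insufficient data, row omitted",
                        sc, v))
        next
      }
      es <- cohen_d_from_summary(gs[[1L]], gs[[2L]], conf = conf,
                                 ci_method = ci_method)
      rnd <- function(x) if (is.null(digits)) x else round(x, digits)
      rows[[length(rows) + 1L]] <- data.frame(
        scale_id = sc, visit = v,
        n_intervention = gs[[1L]]$n, n_control = gs[[2L]]$n,
        change_intervention = gs[[1L]]$mean_change,
        sd_intervention = gs[[1L]]$sd_change,
        change_control = gs[[2L]]$mean_change,
        sd_control = gs[[2L]]$sd_change,
        d = rnd(es$d), ci_low = rnd(es$ci_low), ci_high = rnd(es$ci_high),
        p_value = es$p_value, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
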