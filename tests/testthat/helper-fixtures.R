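# Shared fixture builders and independent oracles.

# A response sheet for a uniform-items definition, all answered `value`.
uniform_responses <- function(def, value, patient_id = "P1",
                              visit = "baseline") {
  data.frame(patient_id = patient_id, scale_id = def$scale_id,
             item_id = def$items$item_id, visit = visit, value = value,
             stringsAsFactors = FALSE)
}

simple_def <- function(n = 10L, lo = 1L, hi = 5L, standardize = TRUE,
                       threshold = 70, mcid = 8) {
  scale_definition("test_scale",
                   data.frame(item_id = sprintf("q%02d", seq_len(n)),
                              response_min = lo, response_max = hi),
                   standardize = standardize,
                   threshold_insufficient = threshold, mcid = mcid)
}

# Construct a sample with exactly the requested mean and SD.
sample_with_moments <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# Brute-force Cohen's d from two raw samples (pooled SD).
brute_force_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# Independent REML log-likelihood for the random-intercept model
# y_ij = b0 + b1 week_ij + u_i + e_ij, evaluated at given variance
# components via per-subject Woodbury identities, with the fixed effects
# profiled out by GLS. Constant terms are kept consistent across calls,
# which is all the grid-comparison tests need.
reml_loglik_ri <- function(data, sigma_u2, sigma_e2,
                           outcome = "y", week = "week",
                           id = "patient_id") {
  ids <- factor(data[[id]])
  X <- cbind(1, data[[week]])
  y <- data[[outcome]]
  XtVX <- matrix(0, 2, 2)
  XtVy <- numeric(2)
  logdet <- 0
  for (g in levels(ids)) {
    sel <- ids == g
    ni <- sum(sel)
    Xi <- X[sel, , drop = FALSE]
    yi <- y[sel]
    # V_i^{-1} = (1/se2) (I - su2/(se2 + ni su2) J)
    c1 <- 1 / sigma_e2
    c2 <- sigma_u2 / (sigma_e2 * (sigma_e2 + ni * sigma_u2))
    Vx <- c1 * Xi - c2 * matrix(colSums(Xi), ni, 2, byrow = TRUE)
    XtVX <- XtVX + t(Xi) %*% Vx
    XtVy <- XtVy + t(Vx) %*% yi
    logdet <- logdet + (ni - 1) * log(sigma_e2) +
      log(sigma_e2 + ni * sigma_u2)
  }
  beta <- solve(XtVX, XtVy)
  quad <- 0
  for (g in levels(ids)) {
    sel <- ids == g
    ni <- sum(sel)
    ri <- y[sel] - X[sel, , drop = FALSE] %*% beta
    c1 <- 1 / sigma_e2
    c2 <- sigma_u2 / (sigma_e2 * (sigma_e2 + ni * sigma_u2))
    quad <- quad + c1 * sum(ri^2) - c2 * sum(ri)^2
  }
  -0.5 * (logdet + determinant(XtVX, logarithm = TRUE)$modulus + quad)
}

# Balanced random-intercept trajectory data with known truth.
simulate_trajectories <- function(n_subjects = 11, weeks = 8,
                                  intercept = 92, slope = -0.95,
                                  sigma_u = 10, sigma_e = 8) {
  u <- stats::rnorm(n_subjects, 0, sigma_u)
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    week <- seq_len(weeks)
    data.frame(patient_id = sprintf("P%02d", i), week = week,
               y = intercept + slope * week + u[i] +
                 stats::rnorm(weeks, 0, sigma_e))
  }))
}

# Covariates mimicking the trial cohort's marginals, for randomization
# balance simulations.
simulate_enrollment <- function(n = 27) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = sample(c(50, 65), n, replace = TRUE, prob = c(0.66, 0.34)),
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(0.56, 0.44)),
    nyha = sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = c(0.24, 0.60, 0.16)),
    stringsAsFactors = FALSE
  )
}

# Total marginal imbalance of an assignment: sum over factor levels of
# |n_armA - n_armB| among patients at that level.
marginal_imbalance <- function(enrollment, arms,
                               labels = c("intervention", "control")) {
  total <- 0
  enrollment$age_lv <- ifelse(enrollment$age < 60, "<60", ">=60")
  for (f in c("age_lv", "sex", "nyha")) {
    for (lv in unique(enrollment[[f]])) {
      sel <- enrollment[[f]] == lv
      total <- total + abs(sum(arms[sel] == labels[1]) -
                             sum(arms[sel] == labels[2]))
    }
  }
  total
}
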