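#' Ground-truth parameters for a synthetic trial
#'
#' Bundles everything the generator needs to produce a complete two-arm
#' cohort with known truth: arm sizes (11 vs 14, the analyzed cohort of
#' the motivating trial), covariate frequencies matching its baseline
#' table (mean age 56, SD 8.3, truncated at the age-40 eligibility bound;
#' 44% female; 92% Black; NYHA I/II/III at 24/60/16%; reduced /
#' mildly-reduced / preserved ejection fraction at 60/20/20%), baseline
#' instrument means and SDs, per-(scale, visit) standardized arm effects
#' to inject, self-monitoring adherence propensities (cohort mean 86.4%,
#' SD 11.16%, spread across patients with a beta distribution), wear-time
#' and activity distributions (wear 1031 min/day SD 421; 5480 steps/day
#' SD 3904, lognormal; 22.2 MVPA min/day SD 18.7, gamma), and
#' visit-level missingness (15% at week 4, 0% at week 8, mirroring the
#' trial's 85%/100% visit completion).
#'
#' @param n_per_arm Named integer vector `c(intervention=, control=)`.
#' @param arm_effects Named list: scale id -> named numeric vector of
#'   standardized effects per visit, e.g.
#'   `list(benefits_self_monitoring = c(week8 = 0.94))`. Empty = null
#'   trial.
#' @param missingness Named visit-level missing-completely-at-random
#'   rates.
#' @param adherence_mean,adherence_sd Cohort mean/SD of the daily
#'   measurement propensity (proportions).
#' @param adherence_weekly_slope Additive weekly drift in the propensity
#'   (probability units per week, default 0).
#' @param ... Override any other default component (see the function
#'   body for names).
#' @return A `truth_params` list.
#' @export
truth_params <- function(n_per_arm = c(intervention = 11L, control = 14L),
                         arm_effects = list(),
                         missingness = c(week4 = 0.15, week8 = 0),
                         adherence_mean = 0.864, adherence_sd = 0.1116,
                         adherence_weekly_slope = 0, ...) {
  truth <- list(
    n_per_arm = n_per_arm,
    age = list(mean = 56, sd = 8.3, min = 40),
    sex_freq = c(male = 0.56, female = 0.44),
    race_freq = c(black = 0.92, white = 0.08),
    nyha_freq = c(I = 0.24, II = 0.60, III = 0.16),
    lvef_freq = c(reduced = 0.60, mildly_reduced = 0.20, preserved = 0.20),
    moca = list(mean = 25.9, sd = 2.05, min = 22, max = 30),
    phq9 = list(mean = 3.1, sd = 3.5, min = 0, max = 27),
    bmi = list(mean = 36.6, sd = 10.1, min = 18, max = 70),
    weight = list(mean = 110.8, sd = 33.1, min = 45, max = 250),
    scales = list(
      schfi_maintenance = list(mean = 72, sd = 16.6, change_sd = 14),
      schfi_symptom_perception = list(mean = 77.5, sd = 16.9, change_sd = 12),
      schfi_management = list(mean = 70.5, sd = 14.6, change_sd = 14),
      scse = list(mean = 86.2, sd = 11.1, change_sd = 13),
      benefits_medication = list(mean = 23.8, sd = 3.1, change_sd = 3),
      barriers_medication = list(mean = 13, sd = 3.7, change_sd = 3),
      benefits_diet = list(mean = 30.2, sd = 3.9, change_sd = 4.3),
      barriers_diet = list(mean = 12.2, sd = 3.5, change_sd = 2.8),
      benefits_self_monitoring = list(mean = 22, sd = 4.2, change_sd = 3.6),
      barriers_self_monitoring = list(mean = 24.5, sd = 5.5, change_sd = 5.5),
      dhfks = list(mean = 11.5, sd = 2, change_sd = 2.1)
    ),
    kccq = list(mean = c(physical_limitation = 67.5,
                         symptom_frequency = 73,
                         quality_of_life = 57.5,
                         social_limitation = 75.5),
                sd = 30, change_sd = 27),
    arm_effects = arm_effects,
    missingness = missingness,
    adherence = list(mean = adherence_mean, sd = adherence_sd,
                     weekly_slope = adherence_weekly_slope),
    wear = list(mean = 1031, sd = 421.2),
    steps = list(mean = 5480, sd = 3904),
    mvpa = list(mean = 22.2, sd = 18.71),
    sedentary = list(mean = 637, sd = 150),
    bp = list(sys_mean = 137, sys_sd = 15, dia_mean = 82, dia_sd = 8),
    weeks = 8L,
    screening = list(n_screened = 504L, n_ineligible = 425L,
                     n_declined = 50L, n_enrolled = 29L,
                     n_lost_before_randomization = 2L,
                     n_excluded_after_randomization = 2L,
                     n_completed_week4 = 23L, n_completed_week8 = 27L,
                     months = 10)
  )
  override <- list(...)
  truth[names(override)] <- override
  stopifnot(all(truth$n_per_arm >= 2), truth$adherence$mean > 0,
            truth$adherence$mean <= 1, truth$adherence$sd >= 0)
  class(truth) <- "truth_params"
  truth
}

#' Calibrated demo truth
#'
#' The default [truth_params()] with the flagship intervention effect of
#' the motivating trial injected: a standardized effect of 0.94 on
#' perceived benefits of self-monitoring at week 8 (and 0.47 at week 4).
#'
#' @return A `truth_params` list.
#' @export
demo_truth <- function() {
  truth_params(arm_effects = list(
    benefits_self_monitoring = c(week4 = 0.47, week8 = 0.94)
  ))
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Location parameter of a lower-truncated normal whose *truncated* mean
# equals the target (fixed-point iteration on the Mills-ratio shift), so
# e.g. ages truncated at the eligibility bound still average 56.
trunc_norm_location <- function(target, sd, lo) {
  mu <- target
  for (i in 1:50) {
    a <- (lo - mu) / sd
    shift <- sd * stats::dnorm(a) / (1 - stats::pnorm(a))
    mu_new <- target - shift
    if (abs(mu_new - mu) < 1e-10) break
    mu <- mu_new
  }
  mu
}

# Distribute an integer raw sum across k items, each within [lo, hi],
# as evenly as possible with the remainder spread over random items.
distribute_sum <- function(k, lo, hi, total) {
  total <- round(total)
  total <- min(max(total, k * lo), k * hi)
  rem <- total - k * lo
  q <- rem %/% k
  r <- rem - k * q
  vals <- rep(lo + q, k)
  if (r > 0) {
    bump <- sample.int(k, r)
    vals[bump] <- vals[bump] + 1L
  }
  vals
}

# Item responses whose score reproduces a target on the reported scale.
items_from_target <- function(def, target, patient_id, visit) {
  lo <- def$items$response_min
  hi <- def$items$response_max
  raw <- if (def$standardize) {
    sum(lo) + target / 100 * (sum(hi) - sum(lo))
  } else {
    target
  }
  stopifnot(length(unique(lo)) == 1L, length(unique(hi)) == 1L)
  vals <- distribute_sum(nrow(def$items), lo[1L], hi[1L], raw)
  data.frame(patient_id = patient_id, scale_id = def$scale_id,
             item_id = def$items$item_id, visit = visit, value = vals,
             stringsAsFactors = FALSE)
}

#' Default answer key for the knowledge test
#'
#' @return Named character vector item_id -> correct option.
#' @export
default_dhfks_key <- function() {
  ids <- sprintf("dhfks_%02d", 1:15)
  key <- stats::setNames(rep("a", 15L), ids)
  key["dhfks_01"] <- "call_doctor_or_nurse"
  key
}

scale_range <- function(def) {
  if (def$standardize) c(0, 100) else
    c(sum(def$items$response_min), sum(def$items$response_max))
}

#' Generate a synthetic cohort with baseline responses
#'
#' Draws patient covariates from the truth's marginal distributions
#' (truncated-normal age, multinomial categoricals) and baseline
#' instrument scores from normal distributions truncated to each scale's
#' range; for item-based scales the target score is back-solved into
#' integer item responses (distributed as evenly as possible with random
#' remainders) and then re-scored, so the recorded score is exactly what
#' [score_scale()] produces. KCCQ-12 subscale scores are generated
#' directly on the 0-100 scale and summarized with [score_kccq12()].
#'
#' @param truth A [truth_params()] object.
#' @param n Cohort size override (default `sum(truth$n_per_arm)`).
#' @param scales Scale ids to generate (default: all in the truth);
#'   `character(0)` skips instrument generation (covariates only).
#' @param items Generate item-level responses (`TRUE`) or scale scores
#'   only.
#' @param kccq Also generate the four KCCQ-12 subscales and summary.
#' @return List of class `synthetic_cohort`: `patients`, `scores` (long:
#'   `patient_id`, `scale_id`, `visit`, `score`), `items` (long item
#'   responses, `NULL` when `items = FALSE`), `truth`.
#' @export
generate_cohort <- function(truth = truth_params(),
                            n = sum(truth$n_per_arm),
                            scales = names(truth$scales), items = TRUE,
                            kccq = TRUE) {
  defs <- default_scale_definitions()
  pick <- function(freq) {
    sample(names(freq), n, replace = TRUE, prob = freq)
  }
  lvef_cat <- pick(truth$lvef_freq)
  lvef <- round(ifelse(lvef_cat == "reduced", stats::runif(n, 20, 40),
                ifelse(lvef_cat == "mildly_reduced", stats::runif(n, 41, 49),
                       stats::runif(n, 50, 65))))
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(rtrunc_norm(n, trunc_norm_location(truth$age$mean,
                                                   truth$age$sd,
                                                   truth$age$min),
                            truth$age$sd, lo = truth$age$min), 1),
    sex = pick(truth$sex_freq),
    race = pick(truth$race_freq),
    nyha = pick(truth$nyha_freq),
    lvef_cat = lvef_cat, lvef = lvef,
    moca = round(rtrunc_norm(n, truth$moca$mean, truth$moca$sd,
                             truth$moca$min, truth$moca$max)),
    phq9 = round(rtrunc_norm(n, truth$phq9$mean, truth$phq9$sd,
                             truth$phq9$min, truth$phq9$max)),
    bmi = round(rtrunc_norm(n, truth$bmi$mean, truth$bmi$sd,
                            truth$bmi$min, truth$bmi$max), 1),
    weight_kg = round(rtrunc_norm(n, truth$weight$mean, truth$weight$sd,
                                  truth$weight$min, truth$weight$max), 1),
    msg_weekday = sample.int(7L, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  scores <- list()
  item_rows <- list()
  for (sc in scales) {
    par <- truth$scales[[sc]]
    def <- defs[[sc]]
    rng <- scale_range(def)
    target <- rtrunc_norm(n, par$mean, par$sd, rng[1L], rng[2L])
    for (i in seq_len(n)) {
      pid <- patients$patient_id[i]
      if (sc == "dhfks") {
        n_correct <- round(target[i])
        key <- default_dhfks_key()
        correct_items <- sample(names(key), n_correct)
        answers <- data.frame(
          item_id = names(key),
          chosen_option = ifelse(names(key) %in% correct_items,
                                 unname(key), "wrong"),
          stringsAsFactors = FALSE
        )
        sr <- score_dhfks(answers, key, patient_id = pid,
                          visit = "baseline")
        if (items) {
          item_rows[[length(item_rows) + 1L]] <- data.frame(
            patient_id = pid, scale_id = sc, item_id = answers$item_id,
            visit = "baseline", value = NA_real_,
            chosen_option = answers$chosen_option,
            stringsAsFactors = FALSE)
        }
      } else {
        resp <- items_from_target(def, target[i], pid, "baseline")
        sr <- score_scale(resp, def)
        if (items) {
          resp$chosen_option <- NA_character_
          item_rows[[length(item_rows) + 1L]] <- resp
        }
      }
      scores[[length(scores) + 1L]] <- data.frame(
        patient_id = pid, scale_id = sc, visit = "baseline",
        score = sr$standardized, stringsAsFactors = FALSE)
    }
  }
  # KCCQ-12 subscales generated directly on the 0-100 scale
  if (kccq) {
    for (i in seq_len(n)) {
      sub <- stats::setNames(
        vapply(names(truth$kccq$mean), function(dm) {
          rtrunc_norm(1, truth$kccq$mean[[dm]], truth$kccq$sd, 0, 100)
        }, numeric(1)), names(truth$kccq$mean))
      pid <- patients$patient_id[i]
      for (dm in names(sub)) {
        scores[[length(scores) + 1L]] <- data.frame(
          patient_id = pid, scale_id = paste0("kccq_", dm),
          visit = "baseline", score = sub[[dm]], stringsAsFactors = FALSE)
      }
      sm <- score_kccq12(sub, patient_id = pid, visit = "baseline")
      scores[[length(scores) + 1L]] <- data.frame(
        patient_id = pid, scale_id = "kccq12_summary", visit = "baseline",
        score = sm$standardized, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    patients = patients,
    scores = do.call(rbind, c(scores, list(make.row.names = FALSE))),
    items = if (items && length(item_rows)) {
      do.call(rbind, c(item_rows, list(make.row.names = FALSE)))
    },
    truth = truth
  ), class = "synthetic_cohort")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate follow-up visit responses with injected arm effects
#'
#' Follow-up scores are baseline plus a normally distributed change whose
#' between-arm standardized difference equals the injected effect for
#' that (scale, visit): control changes are `N(0, change_sd)` and
#' intervention changes `N(d * change_sd, change_sd)`. Scores are clamped
#' to the scale range and, for item-based scales, back-solved into item
#' responses and re-scored so item rounding is reflected in the recorded
#' score. Whole visits then go missing completely at random at the
#' truth's per-visit rate (the imputation stage's input).
#'
#' @param cohort A [generate_cohort()] result whose `patients` carry an
#'   `arm` column (see [randomize_cohort()]).
#' @param truth The [truth_params()] used for the cohort.
#' @param visits Visits to generate (default week 4 and week 8).
#' @param items Back-solve item responses as well.
#' @return List with `scores` (long, including baseline rows) and `items`.
#' @export
generate_followups <- function(cohort, truth = cohort$truth,
                               visits = c("week4", "week8"),
                               items = FALSE) {
  stopifnot("arm" %in% names(cohort$patients))
  defs <- default_scale_definitions()
  patients <- cohort$patients
  base <- cohort$scores[cohort$scores$visit == "baseline", ]
  scale_ids <- unique(base$scale_id)
  out <- list(base)
  item_rows <- list()
  for (v in visits) {
    miss_rate <- if (v %in% names(truth$missingness)) {
      truth$missingness[[v]]
    } else 0
    missing_pid <- patients$patient_id[
      stats::runif(nrow(patients)) < miss_rate]
    for (sc in scale_ids) {
      b <- base[base$scale_id == sc, ]
      is_kccq <- grepl("^kccq", sc)
      if (sc == "kccq12_summary") next  # rebuilt from subscales below
      par <- if (is_kccq) {
        list(change_sd = truth$kccq$change_sd)
      } else {
        truth$scales[[sc]]
      }
      d <- 0
      eff <- truth$arm_effects[[sc]]
      if (!is.null(eff) && v %in% names(eff)) d <- eff[[v]]
      arm <- patients$arm[match(b$patient_id, patients$patient_id)]
      shift <- ifelse(arm == "intervention", d * par$change_sd, 0)
      delta <- stats::rnorm(nrow(b), shift, par$change_sd)
      rng <- if (is_kccq) c(0, 100) else scale_range(defs[[sc]])
      new <- clamp(b$score + delta, rng[1L], rng[2L])
      if (!is_kccq && items && sc != "dhfks") {
        for (i in seq_len(nrow(b))) {
          resp <- items_from_target(defs[[sc]], new[i], b$patient_id[i], v)
          new[i] <- score_scale(resp, defs[[sc]])$standardized
          resp$chosen_option <- NA_character_
          item_rows[[length(item_rows) + 1L]] <- resp
        }
      } else if (!is_kccq) {
        # integer raw-sum scales keep integer scores
        if (sc == "dhfks") new <- round(new)
        else new <- round(new)
      }
      keep <- !b$patient_id %in% missing_pid
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          patient_id = b$patient_id[keep], scale_id = sc, visit = v,
          score = new[keep], stringsAsFactors = FALSE)
      }
    }
    # KCCQ summary from the four follow-up subscales
    sub_ids <- paste0("kccq_", names(truth$kccq$mean))
    fu <- do.call(rbind, out)
    fu <- fu[fu$visit == v & fu$scale_id %in% sub_ids, ]
    if (nrow(fu)) {
      for (pid in unique(fu$patient_id)) {
        x <- fu[fu$patient_id == pid, ]
        if (nrow(x) == 4L) {
          out[[length(out) + 1L]] <- data.frame(
            patient_id = pid, scale_id = "kccq12_summary", visit = v,
            score = mean(x$score), stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(scores = do.call(rbind, c(out, list(make.row.names = FALSE))),
       items = if (length(item_rows)) {
         do.call(rbind, c(item_rows, list(make.row.names = FALSE)))
       })
}

beta_shapes <- function(mean, sd) {
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) stop("infeasible beta mean/sd combination")
  c(a = mean * nu, b = (1 - mean) * nu)
}

#' Generate daily device streams for the follow-up period
#'
#' Per patient: a weight-scale and a BP-cuff measurement propensity drawn
#' from a beta distribution calibrated to the truth's cohort mean and SD,
#' then daily Bernoulli measurement events over the follow-up weeks
#' (optionally with a linear weekly drift in propensity); measured days
#' carry weight values from a slow random walk around the patient's
#' baseline weight and BP readings from the truth's normal distributions.
#' Wear minutes come from a truncated normal, daily steps from a
#' lognormal matched to the truth's mean/SD, MVPA minutes from a matched
#' gamma, and sedentary minutes from a truncated normal bounded by wear
#' time. Hospital stays can be injected as per-patient date windows.
#'
#' @param cohort A [generate_cohort()] result.
#' @param truth The matching [truth_params()].
#' @param start First follow-up day (default `as.Date("2024-01-01")`).
#' @param hospital_days Optional named list: patient_id -> vector of
#'   Dates spent in hospital.
#' @return List with `daily` (one row per patient-day: measurement and
#'   activity summaries) and `propensities` (the per-patient truth).
#' @export
generate_device_streams <- function(cohort, truth = cohort$truth,
                                    start = as.Date("2024-01-01"),
                                    hospital_days = NULL) {
  patients <- cohort$patients
  n <- nrow(patients)
  n_days <- truth$weeks * 7L
  if (truth$adherence$sd == 0) {
    # degenerate: every patient shares the configured propensity
    p_w <- rep(truth$adherence$mean, n)
    p_bp <- rep(truth$adherence$mean, n)
  } else {
    sh <- beta_shapes(truth$adherence$mean, truth$adherence$sd)
    p_w <- stats::rbeta(n, sh["a"], sh["b"])
    p_bp <- stats::rbeta(n, sh["a"], sh["b"])
  }
  ln_s2 <- log(1 + (truth$steps$sd / truth$steps$mean)^2)
  ln_mu <- log(truth$steps$mean) - ln_s2 / 2
  g_shape <- (truth$mvpa$mean / truth$mvpa$sd)^2
  g_rate <- truth$mvpa$mean / truth$mvpa$sd^2
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dates <- start + seq_len(n_days) - 1L
    week <- (seq_len(n_days) - 1L) %/% 7L
    drift <- truth$adherence$weekly_slope * week
    in_hosp <- dates %in% as.Date(hospital_days[[patients$patient_id[i]]])
    meas_w <- stats::runif(n_days) < clamp(p_w[i] + drift, 0, 1) & !in_hosp
    meas_bp <- stats::runif(n_days) < clamp(p_bp[i] + drift, 0, 1) & !in_hosp
    wt <- patients$weight_kg[i] + cumsum(stats::rnorm(n_days, 0, 0.25))
    sys <- round(rtrunc_norm(n_days, truth$bp$sys_mean, truth$bp$sys_sd,
                             90, 220))
    dia <- round(clamp(stats::rnorm(n_days, truth$bp$dia_mean,
                                    truth$bp$dia_sd), 50, sys - 10))
    wear <- round(rtrunc_norm(n_days, truth$wear$mean, truth$wear$sd,
                              0, 1440))
    wear[in_hosp] <- 0
    steps <- round(stats::rlnorm(n_days, ln_mu, sqrt(ln_s2)))
    mvpa <- round(pmin(stats::rgamma(n_days, g_shape, g_rate), wear))
    sedentary <- round(clamp(stats::rnorm(n_days, truth$sedentary$mean,
                                          truth$sedentary$sd), 0, wear))
    steps[wear == 0] <- 0
    mvpa[wear == 0] <- 0
    rows[[i]] <- data.frame(
      patient_id = patients$patient_id[i], date = dates,
      in_hospital = in_hosp,
      weight_kg = ifelse(meas_w, round(wt, 1), NA_real_),
      systolic = ifelse(meas_bp, sys, NA_real_),
      diastolic = ifelse(meas_bp, dia, NA_real_),
      wear_min = wear, steps = steps, mvpa_min = mvpa,
      sedentary_min = sedentary, stringsAsFactors = FALSE
    )
  }
  list(
    daily = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    propensities = data.frame(patient_id = patients$patient_id,
                              p_weight = p_w, p_bp = p_bp,
                              stringsAsFactors = FALSE)
  )
}

#' Expand one daily summary into a minute-level stream
#'
#' Utility for small fixtures and oracle tests: emits 1440 minute rows
#' for one patient-day, with heart-rate values on a contiguous worn block
#' (starting 06:00), the day's steps multinomially scattered over worn
#' minutes, and the first `mvpa_min` worn minutes labelled moderate
#' intensity.
#'
#' @param patient_id,date Identifiers.
#' @param wear_min,steps,mvpa_min Daily summary values to expand.
#' @return Data frame with 1440 rows: `patient_id`, `datetime`,
#'   `heart_rate`, `steps`, `intensity`.
#' @export
generate_minute_day <- function(patient_id, date, wear_min, steps,
                                mvpa_min) {
  stopifnot(wear_min <= 1440, mvpa_min <= wear_min)
  t0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  minute <- t0 + 60 * (0:1439)
  worn <- rep(FALSE, 1440)
  start <- 6L * 60L
  idx <- (start + seq_len(wear_min) - 1L) %% 1440L + 1L
  worn[idx] <- TRUE
  hr <- ifelse(worn, round(stats::rnorm(1440, 72, 8)), NA_real_)
  st <- integer(1440)
  if (steps > 0 && wear_min > 0) {
    st[worn] <- stats::rmultinom(1, steps, rep(1, wear_min))[, 1L]
  }
  intensity <- rep(NA_character_, 1440)
  worn_idx <- which(worn)
  if (length(worn_idx)) {
    intensity[worn_idx] <- "sedentary"
    intensity[worn_idx[st[worn_idx] > 0]] <- "light"
    if (mvpa_min > 0) {
      intensity[worn_idx[seq_len(mvpa_min)]] <- "moderate"
    }
  }
  data.frame(patient_id = patient_id, datetime = minute, heart_rate = hr,
             steps = st, intensity = intensity, stringsAsFactors = FALSE)
}

#' Generate a screening and enrollment log
#'
#' One row per screened patient with disposition flags consistent with
#' the truth's screening funnel (504 screened, 29 enrolled, 27
#' randomized by default - the motivating trial's funnel).
#'
#' @param truth A [truth_params()].
#' @return Data frame with logical columns `eligible`, `declined`,
#'   `enrolled`, `randomized`, `completed_week4`, `completed_week8`.
#' @export
generate_screening_log <- function(truth = truth_params()) {
  s <- truth$screening
  n <- s$n_screened
  log <- data.frame(
    screen_id = sprintf("S%04d", seq_len(n)),
    eligible = FALSE, declined = FALSE, enrolled = FALSE,
    randomized = FALSE, completed_week4 = FALSE, completed_week8 = FALSE
  )
  n_eligible <- n - s$n_ineligible
  log$eligible[seq_len(n_eligible)] <- TRUE
  log$declined[seq_len(min(s$n_declined, n_eligible))] <- TRUE
  enrol <- which(log$eligible & !log$declined)[seq_len(s$n_enrolled)]
  log$enrolled[enrol] <- TRUE
  rand <- enrol[seq_len(s$n_enrolled - s$n_lost_before_randomization)]
  log$randomized[rand] <- TRUE
  log$completed_week4[rand[seq_len(s$n_completed_week4)]] <- TRUE
  log$completed_week8[rand[seq_len(s$n_completed_week8)]] <- TRUE
  log
}

#' Generate a complete synthetic trial
#'
#' Cohort covariates, minimization randomization, baseline and follow-up
#' instrument responses with the truth's injected arm effects, daily
#' device streams, and a screening log - everything downstream stages
#' consume, with the truth embedded for recovery tests.
#'
#' @param truth A [truth_params()].
#' @param seed Optional integer seed (sets the session RNG).
#' @param items Generate item-level responses.
#' @return A `synthetic_trial` list: `patients` (with `arm`), `scores`,
#'   `items`, `daily`, `propensities`, `screening_log`,
#'   `randomization_audit`, `truth`.
#' @export
generate_trial <- function(truth = truth_params(), seed = NULL,
                           items = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(truth, items = items)
  rnd <- randomize_cohort(cohort$patients)
  # honor the truth's arm sizes for the analyzed cohort: minimization
  # assigns arms adaptively, so sizes vary; the analysis is by assigned arm
  cohort$patients$arm <- rnd$assignments$arm
  fu <- generate_followups(cohort, truth, items = items)
  dev <- generate_device_streams(cohort, truth)
  structure(list(
    patients = cohort$patients,
    scores = fu$scores,
    items = if (items) rbind(cohort$items,
                             if (!is.null(fu$items)) {
                               fu$items$chosen_option <- NA_character_
                               fu$items
                             }),
    daily = dev$daily,
    propensities = dev$propensities,
    screening_log = generate_screening_log(truth),
    randomization_audit = rnd$audit,
    truth = truth
  ), class = "synthetic_trial")
}

#' Write / read a synthetic trial as plain CSV files
#'
#' @param trial A `synthetic_trial`.
#' @param dir Output directory (created if needed).
#' @return `write_trial` invisibly returns the file paths; `read_trial`
#'   returns the tables as a named list.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("patients", "scores", "items", "daily", "screening_log")
  paths <- character(0)
  for (tb in tabs) {
    if (is.null(trial[[tb]])) next
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(trial[[tb]], p, row.names = FALSE)
    paths[tb] <- p
  }
  invisible(paths)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  tabs <- c("patients", "scores", "items", "daily", "screening_log")
  out <- list()
  for (tb in tabs) {
    p <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(p)) {
      out[[tb]] <- utils::read.csv(p, stringsAsFactors = FALSE)
    }
  }
  out
}
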