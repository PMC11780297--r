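#' Default pipeline configuration
#'
#' @param seed Integer seed (required for any stochastic stage).
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @param truth A [truth_params()] object (default [demo_truth()], which
#'   injects the calibrated week-8 effect of 0.94 on perceived benefits
#'   of self-monitoring).
#' @param m Number of multiple imputations for missing visit scores.
#' @param min_valid_days Valid-week threshold for activity summaries.
#' @param ci_method Effect-size confidence interval method (`"t"` or
#'   `"normal"`).
#' @return A `run_config` list.
#' @export
run_config <- function(seed, outdir = NULL, truth = demo_truth(),
                       m = 20L, min_valid_days = 3L, ci_method = "t") {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(
        as.integer(seed)))) {
    stop("config requires an integer seed")
  }
  stopifnot(m >= 2, min_valid_days >= 1)
  structure(list(seed = as.integer(seed), outdir = outdir, truth = truth,
                 m = as.integer(m), min_valid_days = min_valid_days,
                 ci_method = ci_method),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed` (required), `outdir`, `m`,
#' `min_valid_days`, `ci_method`, and `arm_effects` (scale -> visit ->
#' standardized effect), which is forwarded into [truth_params()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config requires an integer seed")
  truth <- if (is.null(y$arm_effects)) {
    demo_truth()
  } else {
    truth_params(arm_effects = lapply(y$arm_effects, unlist))
  }
  run_config(seed = y$seed, outdir = y$outdir, truth = truth,
             m = y$m %||% 20L,
             min_valid_days = y$min_valid_days %||% 3L,
             ci_method = y$ci_method %||% "t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full trial pipeline on a synthetic cohort
#'
#' One reproducible run of every stage: simulate the cohort (covariates,
#' minimization randomization, instrument responses with the configured
#' injected effects, device streams, screening log), evaluate the
#' tailoring rules and build each intervention patient's message
#' schedule, compute self-monitoring adherence and weekly activity
#' summaries with their random-intercept trajectory models, impute
#' missing visit scores (when any) and build the outcome tables with
#' pooled-SD effect sizes, and compute feasibility metrics. When the
#' configuration names an output directory every stage's tables are
#' written as CSV plus a JSON results bundle and a run manifest (seed,
#' config hash, package version); a rerun with the same configuration
#' reproduces the outputs exactly.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return A `pipeline_result` list: `trial`, `messages`, `schedules`,
#'   `adherence`, `adherence_lmm`, `weekly_activity`, `results_table`,
#'   `pooled_effects`, `feasibility`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  truth <- config$truth

  ## stage 1: simulate (includes minimization randomization)
  trial <- generate_trial(truth, items = TRUE)
  patients <- trial$patients

  ## stage 2: tailoring for the intervention arm
  rules <- default_message_rules()
  bank <- load_message_bank()
  iv <- patients[patients$arm == "intervention", ]
  messages <- list(); schedules <- list()
  start_date <- as.Date("2024-01-01")
  for (pid in iv$patient_id) {
    resp <- trial$items[trial$items$patient_id == pid &
                          trial$items$visit == "baseline", ]
    fired <- evaluate_rules(resp, rules)
    pref <- list(weekday = iv$msg_weekday[iv$patient_id == pid],
                 time = "10:00")
    sched <- schedule_messages(fired, start_date, weeks = 4L,
                               preference = pref,
                               general_pool = bank$general_pool)
    messages[[pid]] <- fired
    schedules[[pid]] <- sched
  }
  messages <- do.call(rbind, c(messages, list(make.row.names = FALSE)))
  schedules <- do.call(rbind, c(schedules, list(make.row.names = FALSE)))

  ## stage 3: device metrics (intervention arm, like the trial's analysis)
  window <- c(start_date, start_date + truth$weeks * 7L - 1L)
  adher <- lapply(iv$patient_id, function(pid) {
    rec <- trial$daily[trial$daily$patient_id == pid, ]
    list(weight = self_monitoring_adherence(rec, "weight", window),
         bp = self_monitoring_adherence(rec, "bp", window))
  })
  names(adher) <- iv$patient_id
  adherence <- do.call(rbind, lapply(iv$patient_id, function(pid) {
    data.frame(patient_id = pid,
               weight_pct = adher[[pid]]$weight$adherence_pct,
               bp_pct = adher[[pid]]$bp$adherence_pct)
  }))
  weekly_adh <- do.call(rbind, lapply(iv$patient_id, function(pid) {
    w <- adher[[pid]]$weight$weekly_series
    b <- adher[[pid]]$bp$weekly_series
    data.frame(patient_id = pid, week = w$week,
               weight_pct = w$adherence_pct, bp_pct = b$adherence_pct)
  }))
  adherence_lmm <- list(
    weight = fit_random_intercept_lmm(weekly_adh, outcome = "weight_pct"),
    bp = fit_random_intercept_lmm(weekly_adh, outcome = "bp_pct")
  )
  weekly_activity <- weekly_activity_summary(
    trial$daily[trial$daily$patient_id %in% iv$patient_id, ],
    start = start_date, min_valid_days = config$min_valid_days)

  ## stage 4: outcome analysis (intent-to-treat)
  scores <- merge(trial$scores,
                  patients[, c("patient_id", "arm")], by = "patient_id")
  results_table <- build_results_tables(scores, ci_method = config$ci_method)

  ## multiple imputation of missing visit scores, pooled effect per scale
  pooled <- NULL
  wide <- stats::reshape(
    scores[, c("patient_id", "arm", "scale_id", "visit", "score")],
    direction = "wide", idvar = c("patient_id", "arm", "scale_id"),
    timevar = "visit")
  names(wide) <- sub("^score\\.", "", names(wide))
  if (anyNA(wide[c("week4", "week8")])) {
    covs <- patients[, c("patient_id", "age", "sex", "nyha", "lvef",
                         "bmi", "phq9", "moca")]
    pooled_rows <- list()
    for (sc in unique(wide$scale_id)) {
      ws <- merge(wide[wide$scale_id == sc, ], covs, by = "patient_id")
      miss_cols <- c("week4", "week8")[colSums(is.na(
        ws[c("week4", "week8")])) > 0]
      if (!length(miss_cols)) next
      imp <- mi_impute(ws, outcome_cols = c("baseline", "week4", "week8"),
                       predictor_cols = c("arm", "age", "sex", "nyha",
                                          "lvef", "bmi", "phq9", "moca"),
                       m = config$m)
      for (v in miss_cols) {
        est <- vapply(imp$datasets, function(dk) {
          g1 <- group_summary(sum(dk$arm == "intervention"),
                              mean(dk[[v]][dk$arm == "intervention"] -
                                     dk$baseline[dk$arm == "intervention"]),
                              stats::sd(dk[[v]][dk$arm == "intervention"] -
                                          dk$baseline[dk$arm == "intervention"]))
          g2 <- group_summary(sum(dk$arm == "control"),
                              mean(dk[[v]][dk$arm == "control"] -
                                     dk$baseline[dk$arm == "control"]),
                              stats::sd(dk[[v]][dk$arm == "control"] -
                                          dk$baseline[dk$arm == "control"]))
          es <- cohen_d_from_summary(g1, g2, ci_method = config$ci_method)
          c(es$d, es$se_d^2)
        }, numeric(2))
        pr <- rubin_pool(est[1L, ], est[2L, ])
        pooled_rows[[length(pooled_rows) + 1L]] <- data.frame(
          scale_id = sc, visit = v, pooled_d = pr$estimate,
          pooled_se = pr$se, m = pr$m, stringsAsFactors = FALSE)
      }
    }
    pooled <- do.call(rbind, c(pooled_rows, list(make.row.names = FALSE)))
  }

  ## stage 5: feasibility
  feas <- feasibility_metrics(trial$screening_log,
                              months = truth$screening$months)

  manifest <- list(
    seed = config$seed,
    m = config$m,
    min_valid_days = config$min_valid_days,
    ci_method = config$ci_method,
    package_version = as.character(utils::packageVersion("hftrialkit")),
    n_patients = nrow(patients),
    arm_sizes = as.list(table(patients$arm))
  )

  result <- structure(list(
    trial = trial, messages = messages, schedules = schedules,
    adherence = adherence, weekly_adherence = weekly_adh,
    adherence_lmm = adherence_lmm, weekly_activity = weekly_activity,
    results_table = results_table, pooled_effects = pooled,
    feasibility = feas, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$outdir)) {
    write_pipeline_result(result, config$outdir)
  }
  result
}

#' Write a pipeline result bundle to disk
#'
#' CSV per stage table, a JSON results bundle, and `manifest.json`
#' carrying the seed, settings and an MD5 hash of the serialized
#' configuration-relevant fields.
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_trial(result$trial, file.path(outdir, "trial"))
  tabs <- c("messages", "schedules", "adherence", "weekly_adherence",
            "weekly_activity", "results_table", "pooled_effects")
  for (tb in tabs) {
    if (is.null(result[[tb]])) next
    utils::write.csv(result[[tb]], file.path(outdir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  bundle <- list(
    feasibility = unclass(result$feasibility),
    adherence_lmm = lapply(result$adherence_lmm, function(f) {
      list(coefficients = f$coefficients, sigma_u2 = f$sigma_u2,
           sigma_e2 = f$sigma_e2)
    }),
    results_table = result$results_table,
    pooled_effects = result$pooled_effects
  )
  jsonlite::write_json(bundle, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", pretty = TRUE)
  manifest <- result$manifest
  tmp <- tempfile()
  saveRDS(manifest[c("seed", "m", "min_valid_days", "ci_method")], tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
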