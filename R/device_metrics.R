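#' Wear time from minute-level heart-rate samples
#'
#' A wrist tracker is counted as worn in any minute that carries a
#' heart-rate value; daily wear time is the count of such minutes.
#'
#' @param day_samples Data frame of one patient-day of minute samples with
#'   a `heart_rate` column (`NA` when no reading).
#' @return Integer minutes worn, 0-1440.
#' @export
wear_minutes <- function(day_samples) {
  if (is.null(day_samples) || !nrow(day_samples)) return(0L)
  sum(!is.na(day_samples$heart_rate))
}

#' Valid-day rule for wearable data
#'
#' A day enters the activity analysis only with at least 10 hours
#' (600 minutes) of wear time.
#'
#' @param wear_min Numeric vector of daily wear minutes (0-1440).
#' @param threshold Minimum wear minutes (default 600).
#' @return Logical vector.
#' @export
valid_day <- function(wear_min, threshold = 600) {
  stopifnot(all(wear_min >= 0 & wear_min <= 1440, na.rm = TRUE))
  !is.na(wear_min) & wear_min >= threshold
}

#' Weekly activity summaries over valid days
#'
#' Groups daily summaries into consecutive 7-day windows from each
#' patient's start date and computes per-week means of daily steps, MVPA
#' (moderate-to-vigorous physical activity) minutes, sedentary minutes,
#' and wear minutes, using valid days only. Weeks with fewer than
#' `min_valid_days` valid days are reported with `NA` means. The default
#' of 3 valid days reflects the threshold the analysis is run with; a
#' stricter 4-day convention is sometimes used and is available through
#' the argument.
#'
#' @param days Data frame with columns `patient_id`, `date`, `wear_min`,
#'   and any of `steps`, `mvpa_min`, `sedentary_min`.
#' @param start Date the follow-up starts (week 1 = `start` .. `start+6`).
#'   Defaults to the earliest date per patient.
#' @param min_valid_days Minimum valid days for a week to count
#'   (default 3).
#' @param wear_threshold Valid-day wear threshold in minutes.
#' @return Data frame: one row per patient-week with `n_valid_days`, the
#'   per-week means, and a `valid_week` flag.
#' @export
weekly_activity_summary <- function(days, start = NULL,
                                    min_valid_days = 3L,
                                    wear_threshold = 600) {
  days <- as.data.frame(days)
  days$date <- as.Date(days$date)
  out <- lapply(split(days, days$patient_id), function(d) {
    s <- if (is.null(start)) min(d$date) else as.Date(start)
    d$week <- as.integer(d$date - s) %/% 7L + 1L
    d$valid <- valid_day(d$wear_min, wear_threshold)
    vars <- intersect(c("steps", "mvpa_min", "sedentary_min", "wear_min"),
                      names(d))
    do.call(rbind, lapply(split(d, d$week), function(w) {
      nv <- sum(w$valid)
      ok <- nv >= min_valid_days
      means <- vapply(vars, function(v) {
        if (ok) mean(w[[v]][w$valid]) else NA_real_
      }, numeric(1))
      row <- data.frame(patient_id = w$patient_id[1L], week = w$week[1L],
                        n_valid_days = nv, valid_week = ok,
                        stringsAsFactors = FALSE)
      row[paste0("mean_", vars)] <- as.list(means)
      row
    }))
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$patient_id, res$week), , drop = FALSE]
}

#' Daily self-monitoring adherence for a device modality
#'
#' Adherence is the percentage of protocol-required days on which the
#' patient took at least one measurement with the given modality (body
#' weight scale or blood-pressure cuff), after removing in-hospital days
#' from the denominator. A weekly series (7-day windows from the window
#' start) is returned for trajectory modelling.
#'
#' @param records Data frame of daily device records: `patient_id`,
#'   `date`, measurement columns (`weight_kg` for weight; `systolic` and
#'   `diastolic` for BP), and optionally `in_hospital`.
#' @param modality `"weight"` or `"bp"`.
#' @param window Length-2 vector of dates (start, end), inclusive.
#' @return List of class `adherence_summary`: `patient_id`,
#'   `eligible_days`, `adherent_days`, `adherence_pct`, and
#'   `weekly_series` (data frame `week`, `eligible_days`,
#'   `adherent_days`, `adherence_pct`).
#' @export
self_monitoring_adherence <- function(records, modality = c("weight", "bp"),
                                      window) {
  modality <- match.arg(modality)
  records <- as.data.frame(records)
  records$date <- as.Date(records$date)
  window <- as.Date(window)
  all_days <- seq(window[1L], window[2L], by = "day")
  if (is.null(records$in_hospital)) records$in_hospital <- FALSE
  measured_col <- if (modality == "weight") "weight_kg" else "systolic"
  measured_days <- unique(records$date[!is.na(records[[measured_col]])])
  hospital_days <- unique(records$date[records$in_hospital %in% TRUE])
  eligible <- setdiff(all_days, hospital_days)
  eligible <- as.Date(eligible, origin = "1970-01-01")
  if (!length(eligible)) {
    return(structure(list(
      patient_id = records$patient_id[1L], window = window,
      eligible_days = 0L, adherent_days = 0L, adherence_pct = NA_real_,
      weekly_series = NULL), class = "adherence_summary"))
  }
  adherent <- intersect(eligible, measured_days)
  week_of <- function(d) as.integer(as.Date(d, origin = "1970-01-01") -
                                      window[1L]) %/% 7L + 1L
  wk_el <- table(week_of(eligible))
  wk_ad <- table(factor(week_of(adherent), levels = names(wk_el)))
  weekly <- data.frame(
    week = as.integer(names(wk_el)),
    eligible_days = as.integer(wk_el),
    adherent_days = as.integer(wk_ad)
  )
  weekly$adherence_pct <- 100 * weekly$adherent_days / weekly$eligible_days
  structure(list(
    patient_id = if ("patient_id" %in% names(records) &&
                     nrow(records)) records$patient_id[1L] else NA,
    window = window,
    eligible_days = length(eligible),
    adherent_days = length(adherent),
    adherence_pct = 100 * length(adherent) / length(eligible),
    weekly_series = weekly
  ), class = "adherence_summary")
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat(sprintf("<adherence_summary> %s: %d/%d eligible days (%.1f%%)\n",
              x$patient_id, x$adherent_days, x$eligible_days,
              x$adherence_pct))
  invisible(x)
}

bp_levels <- c("normal", "elevated", "stage1", "stage2", "crisis")

#' Classify a blood-pressure reading
#'
#' Guideline bands: normal (<120/<80), elevated (120-129 and <80),
#' stage 1 hypertension (130-139 or 80-89), stage 2 hypertension
#' (140-179 or 90-119), hypertensive crisis (>=180 or >=120). When the
#' systolic and diastolic readings imply different bands, the more severe
#' band wins. An emergency flag is raised above 180/110 (either reading),
#' the point at which the companion app tells the patient to seek
#' emergency care.
#'
#' @param systolic,diastolic Numeric vectors (mm Hg); recycled to a
#'   common length.
#' @return Data frame with columns `systolic`, `diastolic`, `category`
#'   (factor with levels normal < elevated < stage1 < stage2 < crisis)
#'   and `emergency` (logical).
#' @export
classify_bp <- function(systolic, diastolic) {
  n <- max(length(systolic), length(diastolic))
  systolic <- rep_len(as.numeric(systolic), n)
  diastolic <- rep_len(as.numeric(diastolic), n)
  if (any(systolic <= 0 | diastolic <= 0, na.rm = TRUE)) {
    stop("blood pressure readings must be positive")
  }
  if (any(systolic <= diastolic, na.rm = TRUE)) {
    stop("non-physiological reading: systolic must exceed diastolic")
  }
  sev_sys <- findInterval(systolic, c(120, 130, 140, 180)) + 1L
  # diastolic has no band of its own in the 'elevated' range
  sev_dia <- findInterval(diastolic, c(80, 90, 120)) + 1L
  sev_dia <- ifelse(sev_dia >= 2L, sev_dia + 1L, sev_dia)
  sev <- pmax(sev_sys, sev_dia)
  data.frame(
    systolic = systolic, diastolic = diastolic,
    category = factor(bp_levels[sev], levels = bp_levels, ordered = TRUE),
    emergency = systolic > 180 | diastolic > 110
  )
}

#' Day-over-day weight-gain alerts
#'
#' Flags any day whose weight exceeds the previous measurement, taken one
#' day earlier, by at least the alert threshold (default 3 lb, about
#' 1.36 kg - the classic "3 pounds in a day" heart-failure warning).
#' Gains accrued across a gap of more than one day do not raise a daily
#' flag but are visible in the reported change since the last
#' measurement.
#'
#' @param series Data frame with columns `date` and `weight_kg`,
#'   date-ordered (rows with missing weight are dropped).
#' @param threshold_kg Daily gain that triggers an alert.
#' @return The series with `change_since_last` (kg, `NA` for the first
#'   row), `days_since_last`, and logical `alert`.
#' @export
weight_change_alert <- function(series, threshold_kg = 3 * 0.45359237) {
  series <- as.data.frame(series)
  series <- series[!is.na(series$weight_kg), , drop = FALSE]
  series$date <- as.Date(series$date)
  series <- series[order(series$date), , drop = FALSE]
  n <- nrow(series)
  series$change_since_last <- c(NA, diff(series$weight_kg))
  series$days_since_last <- c(NA, as.integer(diff(series$date)))
  series$alert <- !is.na(series$change_since_last) &
    series$days_since_last == 1L &
    series$change_since_last >= threshold_kg
  series
}
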