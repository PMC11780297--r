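#' Define a patient-reported-outcome scale
#'
#' A scale definition carries the item metadata needed to score a
#' questionnaire: item identifiers, per-item response ranges, reverse-scoring
#' flags, whether the raw sum is standardized to 0-100, and the clinical
#' thresholds attached to the instrument (insufficiency cutoff and minimal
#' clinically important difference, MCID).
#'
#' @param scale_id Character identifier, e.g. `"schfi_maintenance"`.
#' @param items Data frame with columns `item_id`, `response_min`,
#'   `response_max` and optionally `reverse_scored` (default `FALSE`).
#' @param standardize Logical; map the raw sum onto 0-100 via
#'   `100 * (raw - min) / (max - min)`. Belief scales and knowledge tests
#'   are reported as raw sums and use `FALSE`.
#' @param threshold_insufficient Numeric cutoff on the standardized score
#'   below which the score is flagged clinically insufficient (strict `<`),
#'   or `NULL` when the instrument has none.
#' @param mcid Minimal clinically important difference on the reported
#'   score scale, or `NULL`.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(scale_id, items, standardize = TRUE,
                             threshold_insufficient = NULL, mcid = NULL) {
  stopifnot(is.character(scale_id), length(scale_id) == 1L)
  items <- as.data.frame(items)
  required <- c("item_id", "response_min", "response_max")
  if (!all(required %in% names(items))) {
    stop("items must have columns item_id, response_min, response_max")
  }
  if (nrow(items) == 0L) stop("items must be non-empty")
  if (is.null(items$reverse_scored)) items$reverse_scored <- FALSE
  if (anyDuplicated(items$item_id)) stop("duplicate item_id in definition")
  if (any(items$response_min >= items$response_max)) {
    stop("response_min must be < response_max for every item")
  }
  if (!is.null(mcid) && mcid <= 0) stop("mcid must be > 0 when present")
  structure(
    list(
      scale_id = scale_id,
      items = items[, c("item_id", "response_min", "response_max",
                        "reverse_scored")],
      standardize = isTRUE(standardize),
      threshold_insufficient = threshold_insufficient,
      mcid = mcid
    ),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items, %s\n", x$scale_id,
              nrow(x$items),
              if (x$standardize) "standardized 0-100" else "raw sum"))
  invisible(x)
}

uniform_items <- function(prefix, n, lo = 1L, hi = 5L) {
  data.frame(
    item_id = sprintf("%s_%02d", prefix, seq_len(n)),
    response_min = lo, response_max = hi, reverse_scored = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Default scale definitions for the trial's instrument battery
#'
#' The published instruments are copyrighted, so per-item wording and exact
#' response layouts are not reproduced; these definitions are declared,
#' editable stand-ins that reproduce the scoring behaviour that matters
#' downstream: SCHFI v7.2 subscales (10/9/10 items, standardized 0-100,
#' insufficiency cutoff 70, MCID 8), the 10-item self-care self-efficacy
#' scale (same standardization and cutoffs), three health-belief scales
#' split into benefit and barrier subscales reported as raw sums, and the
#' 15-item knowledge test. All Likert items default to a 1-5 response range.
#'
#' The belief scales are described in the literature as 12-item
#' instruments, but the published subscale score ranges are only attainable
#' with roughly 7 benefit and 6 barrier items on a 1-5 range, so those
#' sizes are used here; they are fixture defaults, not assertions about
#' the licensed instruments.
#'
#' @return Named list of [scale_definition()] objects.
#' @export
default_scale_definitions <- function() {
  std <- function(id, n) {
    scale_definition(id, uniform_items(id, n), standardize = TRUE,
                     threshold_insufficient = 70, mcid = 8)
  }
  raw <- function(id, n) {
    scale_definition(id, uniform_items(id, n), standardize = FALSE)
  }
  list(
    schfi_maintenance = std("schfi_maintenance", 10L),
    schfi_symptom_perception = std("schfi_symptom_perception", 9L),
    schfi_management = std("schfi_management", 10L),
    scse = std("scse", 10L),
    benefits_medication = raw("benefits_medication", 7L),
    barriers_medication = raw("barriers_medication", 6L),
    benefits_diet = raw("benefits_diet", 7L),
    barriers_diet = raw("barriers_diet", 6L),
    benefits_self_monitoring = raw("benefits_self_monitoring", 7L),
    barriers_self_monitoring = raw("barriers_self_monitoring", 6L),
    dhfks = scale_definition("dhfks", uniform_items("dhfks", 15L, 0L, 1L),
                             standardize = FALSE)
  )
}

#' Score one scale for one patient visit
#'
#' Sums the (reverse-corrected) item responses and, when the definition
#' asks for it, standardizes the sum to the 0-100 range with
#' `100 * (raw_sum - min_sum) / (max_sum - min_sum)`. Missing items are
#' counted; when at most half the items are missing the raw sum is
#' prorated (mean of answered items carried to the full item count),
#' otherwise the score is marked missing. No cross-patient imputation
#' happens here; that is the job of the multiple-imputation stage.
#'
#' @param responses Data frame with columns `item_id` and `value` (integer
#'   or `NA`); optionally `patient_id`, `scale_id`, `visit`, which must
#'   each be constant when present.
#' @param def A [scale_definition()].
#' @param prorate_max_missing Largest tolerated fraction of missing items
#'   before the score itself is declared missing (default 0.5).
#' @return One-row data frame of class `scale_score` with columns
#'   `patient_id`, `scale_id`, `visit`, `raw_sum`, `standardized`,
#'   `n_missing_items`.
#' @export
score_scale <- function(responses, def, prorate_max_missing = 0.5) {
  stopifnot(inherits(def, "scale_definition"))
  responses <- as.data.frame(responses)
  for (col in c("patient_id", "scale_id", "visit")) {
    if (col %in% names(responses) &&
        length(unique(responses[[col]])) > 1L) {
      stop(sprintf("responses mix more than one %s", col))
    }
  }
  if (anyDuplicated(responses$item_id)) {
    stop("duplicate item_id in responses")
  }
  unknown <- setdiff(responses$item_id, def$items$item_id)
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  }
  idx <- match(def$items$item_id, responses$item_id)
  value <- responses$value[idx]  # NA for unanswered items
  lo <- def$items$response_min
  hi <- def$items$response_max
  bad <- !is.na(value) & (value < lo | value > hi)
  if (any(bad)) {
    stop("response out of declared range for item(s): ",
         paste(def$items$item_id[bad], collapse = ", "))
  }
  corrected <- ifelse(def$items$reverse_scored, lo + hi - value, value)
  n_items <- nrow(def$items)
  n_missing <- sum(is.na(corrected))
  if (n_missing / n_items > prorate_max_missing) {
    raw_sum <- NA_real_
  } else if (n_missing > 0L) {
    raw_sum <- mean(corrected, na.rm = TRUE) * n_items
  } else {
    raw_sum <- sum(corrected)
  }
  min_sum <- sum(lo)
  max_sum <- sum(hi)
  standardized <- if (def$standardize) {
    100 * (raw_sum - min_sum) / (max_sum - min_sum)
  } else {
    raw_sum
  }
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(responses) &&
                     nrow(responses)) responses$patient_id[1L] else NA,
    scale_id = def$scale_id,
    visit = if ("visit" %in% names(responses) &&
                nrow(responses)) responses$visit[1L] else NA,
    raw_sum = raw_sum,
    standardized = standardized,
    n_missing_items = n_missing,
    stringsAsFactors = FALSE
  )
  class(out) <- c("scale_score", class(out))
  out
}

#' Score a multiple-choice knowledge test
#'
#' The knowledge score is the count of correct answers, 0 to the number of
#' items (15 for the default heart-failure knowledge test); it is never
#' standardized. Missing answers count as not correct but are reported in
#' `n_missing_items`.
#'
#' @param answers Data frame with columns `item_id` and `chosen_option`
#'   (character, `NA` for unanswered).
#' @param key Named character vector mapping `item_id` to the correct
#'   option.
#' @param patient_id,visit Optional identifiers carried into the result.
#' @return A `scale_score` row with `raw_sum` = number correct.
#' @export
score_dhfks <- function(answers, key, patient_id = NA, visit = NA) {
  answers <- as.data.frame(answers)
  unknown <- setdiff(answers$item_id, names(key))
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(answers$item_id)) stop("duplicate item_id in answers")
  idx <- match(names(key), answers$item_id)
  chosen <- answers$chosen_option[idx]
  correct <- !is.na(chosen) & chosen == unname(key)
  out <- data.frame(
    patient_id = patient_id, scale_id = "dhfks", visit = visit,
    raw_sum = sum(correct), standardized = sum(correct),
    n_missing_items = sum(is.na(chosen)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("scale_score", class(out))
  out
}

#' Score the KCCQ-12 summary from its four subscales
#'
#' Each KCCQ-12 subscale (physical limitation, symptom frequency, quality
#' of life, social limitation) is scored 0-100; the summary score is the
#' arithmetic mean of the four. If any subscale is missing the summary is
#' marked missing rather than averaged over fewer domains.
#'
#' @param subscale_scores Named numeric vector or list with entries
#'   `physical_limitation`, `symptom_frequency`, `quality_of_life`,
#'   `social_limitation` (each in 0-100 or `NA`).
#' @param patient_id,visit Optional identifiers carried into the result.
#' @return A `scale_score` row for scale `"kccq12_summary"`.
#' @export
score_kccq12 <- function(subscale_scores, patient_id = NA, visit = NA) {
  needed <- c("physical_limitation", "symptom_frequency",
              "quality_of_life", "social_limitation")
  x <- unlist(subscale_scores)[needed]
  if (any(!is.na(x) & (x < 0 | x > 100))) {
    stop("subscale scores must lie in [0, 100]")
  }
  summary_score <- if (anyNA(x)) NA_real_ else mean(x)
  out <- data.frame(
    patient_id = patient_id, scale_id = "kccq12_summary", visit = visit,
    raw_sum = summary_score, standardized = summary_score,
    n_missing_items = sum(is.na(x)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("scale_score", class(out))
  out
}

#' Attach clinical flags to a scored scale
#'
#' Flags a score as `insufficient` when the standardized value falls
#' strictly below the definition's insufficiency threshold (70 for the
#' self-care and self-efficacy scales), and as a clinically important
#' change (`mcid_change`) when the absolute change from a baseline score
#' reaches the instrument's MCID (8 points for the standardized self-care
#' scales, 5 for the KCCQ-12 summary).
#'
#' @param score A `scale_score` row (or anything with a `standardized`
#'   column/field).
#' @param def The matching [scale_definition()].
#' @param baseline Optional baseline standardized score for MCID flagging.
#' @return The score row with logical columns `insufficient` and
#'   `mcid_change` added (the latter `NA` when no baseline is supplied).
#' @export
classify_score <- function(score, def, baseline = NULL) {
  stopifnot(inherits(def, "scale_definition"))
  std <- score$standardized
  score$insufficient <- if (is.null(def$threshold_insufficient)) {
    FALSE
  } else {
    !is.na(std) & std < def$threshold_insufficient
  }
  score$mcid_change <- if (is.null(baseline) || is.null(def$mcid)) {
    NA
  } else {
    !is.na(std) & !is.na(baseline) & abs(std - baseline) >= def$mcid
  }
  score
}

#' Screen a candidate patient against the trial eligibility criteria
#'
#' Eligibility requires age at least 40 years, NYHA functional class I-III
#' (class IV and undocumented classes fail), a Montreal Cognitive
#' Assessment (MoCA) score of at least 22, and no exclusion flags (e.g.
#' transplant waiting list, end-stage disease, dialysis). Every failed
#' criterion is named in the reasons.
#'
#' @param record List or one-row data frame with fields `age`, `nyha`
#'   (one of `"I"`, `"II"`, `"III"`, `"IV"`), `moca`, and optionally
#'   `exclusions` (character vector of active exclusion flags).
#' @return List with `eligible` (logical) and `reasons` (character vector,
#'   empty when eligible).
#' @export
screen_eligibility <- function(record) {
  record <- as.list(record)
  for (f in c("age", "nyha", "moca")) {
    if (is.null(record[[f]]) || is.na(record[[f]])) {
      stop("missing required field: ", f)
    }
  }
  reasons <- character(0)
  if (record$age < 40) reasons <- c(reasons, "age")
  if (!record$nyha %in% c("I", "II", "III")) reasons <- c(reasons, "nyha")
  if (record$moca < 22) reasons <- c(reasons, "cognition")
  excl <- record$exclusions
  excl <- excl[!is.na(excl) & nzchar(excl)]
  if (length(excl)) reasons <- c(reasons, paste0("exclusion:", excl))
  list(eligible = length(reasons) == 0L, reasons = reasons)
}
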