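#' Construct a tailoring rule
#'
#' A rule links one assessment item to one or more text messages. Likert
#' rules come in two polarities: a `benefit` (or `efficacy`) rule fires
#' when the response is *at or below* its threshold — the patient does not
#' yet perceive the benefit, or lacks confidence — and a `barrier` rule
#' fires when the response is *at or above* its threshold — the patient
#' endorses the barrier. Knowledge rules fire when the chosen option
#' differs from the correct one. At the default threshold of 3 both a
#' benefit and a barrier rule fire on a response of exactly 3.
#'
#' @param rule_id Unique identifier.
#' @param target One of `"medication"`, `"diet"`, `"self_monitoring"`,
#'   `"self_efficacy"`, `"knowledge"`.
#' @param item_id Item the rule inspects.
#' @param kind One of `"benefit"`, `"barrier"`, `"efficacy"`,
#'   `"knowledge"`.
#' @param threshold Likert threshold (ignored for knowledge rules).
#' @param correct_option Correct answer identifier (knowledge rules only).
#' @param message_ids Ordered character vector of messages sent when the
#'   rule fires; multi-message sequences are delivered in this order.
#' @return A `message_rule` list.
#' @export
message_rule <- function(rule_id, target, item_id, kind, threshold = 3L,
                         correct_option = NULL,
                         message_ids = character(0)) {
  target <- match.arg(target, c("medication", "diet", "self_monitoring",
                                "self_efficacy", "knowledge"))
  kind <- match.arg(kind, c("benefit", "barrier", "efficacy", "knowledge"))
  if (kind == "knowledge" && is.null(correct_option)) {
    stop("knowledge rules need a correct_option")
  }
  if (!length(message_ids)) stop("message_ids must be non-empty")
  structure(
    list(rule_id = rule_id, target = target, item_id = item_id,
         kind = kind, threshold = threshold,
         correct_option = correct_option, message_ids = message_ids),
    class = "message_rule"
  )
}

#' Default tailoring rules
#'
#' The shipped rule set covers the sample decision algorithm: a
#' medication-benefit rule ("water pills lower my chance of being in the
#' hospital", fires on answers <= 3), barrier rules for medication, diet
#' and self-monitoring (fire on answers >= 3), a two-message self-efficacy
#' sequence (fires on confidence <= 3), and a knowledge rule that sends an
#' education message unless the patient answers "call the doctor or
#' nurse". Item ids reference [default_scale_definitions()] so the rule
#' set runs directly against generated response sheets.
#'
#' @return List of [message_rule()] objects.
#' @export
default_message_rules <- function() {
  list(
    message_rule("med_benefit_waterpills", "medication",
                 "benefits_medication_01", "benefit",
                 message_ids = "msg_med_benefit_1"),
    message_rule("med_barrier_away_from_home", "medication",
                 "barriers_medication_01", "barrier",
                 message_ids = "msg_med_barrier_1"),
    message_rule("diet_barrier_taste", "diet",
                 "barriers_diet_01", "barrier",
                 message_ids = "msg_diet_barrier_1"),
    message_rule("selfmon_barrier_weighing", "self_monitoring",
                 "barriers_self_monitoring_01", "barrier",
                 message_ids = "msg_selfmon_barrier_1"),
    message_rule("efficacy_confidence_stable", "self_efficacy",
                 "scse_01", "efficacy",
                 message_ids = c("msg_efficacy_1", "msg_efficacy_2")),
    message_rule("knowledge_breathless_action", "knowledge",
                 "dhfks_01", "knowledge",
                 correct_option = "call_doctor_or_nurse",
                 message_ids = "msg_knowledge_1")
  )
}

#' Load the shipped message bank
#'
#' The bank ships the sample tailored messages plus a small placeholder
#' general-education pool used to fill schedule slots when too few rules
#' fire. It is an editable YAML file under `inst/extdata`.
#'
#' @param path Optional path to an alternative YAML bank.
#' @return List with `messages` (named list id -> text) and
#'   `general_pool` (character vector of message ids).
#' @export
load_message_bank <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "message_bank.yaml",
                        package = "hftrialkit")
  }
  bank <- yaml::read_yaml(path)
  bank$general_pool <- unlist(bank$general_pool)
  bank
}

rule_fires <- function(rule, value, option = NA_character_) {
  if (rule$kind == "knowledge") {
    if (is.na(option)) return(NA)
    return(option != rule$correct_option)
  }
  if (is.na(value)) return(NA)
  if (rule$kind == "barrier") value >= rule$threshold else value <= rule$threshold
}

#' Evaluate tailoring rules against a response sheet
#'
#' Applies every rule to the matching item response. Benefit and efficacy
#' rules fire on values at or below the threshold, barrier rules at or
#' above it, knowledge rules on incorrect options. Non-fired rules
#' contribute nothing; rules whose item was not answered are skipped and
#' reported in the `skipped` attribute. Every fired rule emits its full
#' message sequence in order, with the triggering response value recorded
#' as the audit reason.
#'
#' @param responses Data frame with columns `item_id` and `value`
#'   (numeric, `NA` allowed) and, for knowledge items, `chosen_option`;
#'   optionally `patient_id` and `visit`.
#' @param rules List of [message_rule()] objects.
#' @return Data frame of triggered messages: `patient_id`, `rule_id`,
#'   `target`, `message_id`, `seq`, `visit`, `reason`.
#' @export
evaluate_rules <- function(responses, rules = default_message_rules()) {
  responses <- as.data.frame(responses)
  if (!"chosen_option" %in% names(responses)) {
    responses$chosen_option <- NA_character_
  }
  patient <- if ("patient_id" %in% names(responses) &&
                 nrow(responses)) responses$patient_id[1L] else NA
  visit <- if ("visit" %in% names(responses) &&
               nrow(responses)) responses$visit[1L] else NA
  known_items <- responses$item_id
  out <- list()
  skipped <- character(0)
  for (rule in rules) {
    i <- match(rule$item_id, known_items)
    if (is.na(i)) next  # rule's item not on this sheet
    fired <- rule_fires(rule, responses$value[i],
                        responses$chosen_option[i])
    if (is.na(fired)) {
      skipped <- c(skipped, rule$rule_id)
      next
    }
    if (!fired) next
    reason <- if (rule$kind == "knowledge") {
      responses$chosen_option[i]
    } else {
      as.character(responses$value[i])
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = patient, rule_id = rule$rule_id, target = rule$target,
      message_id = rule$message_ids, seq = seq_along(rule$message_ids),
      visit = visit, reason = reason, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(patient_id = character(0), rule_id = character(0),
               target = character(0), message_id = character(0),
               seq = integer(0), visit = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  attr(res, "skipped") <- skipped
  res
}

target_priority <- c("medication", "diet", "self_monitoring",
                     "self_efficacy", "knowledge")

# Round-robin across intervention targets: take one rule at a time from
# each target's queue (priority order above, rule order within target);
# a rule's multi-message sequence stays contiguous and counts as N sends.
interleave_messages <- function(triggered) {
  if (!nrow(triggered)) return(triggered)
  key <- paste(triggered$rule_id, triggered$visit)
  blocks <- split(triggered, factor(key, levels = unique(key)))
  queues <- split(blocks,
                  factor(vapply(blocks, function(b) b$target[1L], ""),
                         levels = target_priority))
  queues <- Filter(length, queues)
  out <- list()
  while (length(queues)) {
    for (tg in names(queues)) {
      out[[length(out) + 1L]] <- queues[[tg]][[1L]]
      queues[[tg]] <- queues[[tg]][-1L]
    }
    queues <- Filter(length, queues)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Build a weekly message delivery schedule
#'
#' Fired messages are queued round-robin across intervention targets
#' (medication, diet, self-monitoring, self-efficacy, knowledge) so each
#' week mixes topics, then delivered at the trial rate of 4 messages per
#' week on the patient's preferred weekday and time until the queue is
#' exhausted. Remaining slots are filled from a general-education pool
#' (cycled); if nothing fired at all the whole schedule comes from the
#' pool. The schedule is deterministic given its inputs.
#'
#' @param triggered Data frame from [evaluate_rules()].
#' @param start Date the schedule starts.
#' @param weeks Number of weeks to schedule.
#' @param preference List with `weekday` (1 = Monday .. 7 = Sunday) and
#'   `time` (`"HH:MM"`).
#' @param rate Messages per week (default 4).
#' @param general_pool Character vector of filler message ids.
#' @return Data frame of class `message_schedule`: `patient_id`, `week`,
#'   `datetime`, `slot`, `message_id`, `rule_id`.
#' @export
schedule_messages <- function(triggered, start, weeks,
                              preference = list(weekday = 1L,
                                                time = "10:00"),
                              rate = 4L, general_pool = character(0)) {
  stopifnot(weeks >= 1)
  start <- as.Date(start)
  queue <- interleave_messages(triggered)
  ids <- queue$message_id
  rule_ids <- queue$rule_id
  n_slots <- weeks * rate
  if (length(ids) < n_slots) {
    n_fill <- n_slots - length(ids)
    if (length(general_pool)) {
      fill <- rep_len(general_pool, n_fill)
      ids <- c(ids, fill)
      rule_ids <- c(rule_ids, rep("general_pool", n_fill))
    }
  }
  n <- min(length(ids), n_slots)
  if (n == 0L) {
    sched <- data.frame(patient_id = character(0), week = integer(0),
                        datetime = as.POSIXct(character(0), tz = "UTC"),
                        slot = integer(0), message_id = character(0),
                        rule_id = character(0))
    class(sched) <- c("message_schedule", class(sched))
    return(sched)
  }
  slot <- seq_len(n)
  week <- (slot - 1L) %/% rate + 1L
  # first preferred weekday on/after the start date, then weekly
  offset <- (preference$weekday - as.integer(format(start, "%u"))) %% 7L
  day <- start + offset + (week - 1L) * 7L
  datetime <- as.POSIXct(paste(day, preference$time), tz = "UTC")
  patient <- if (nrow(queue)) queue$patient_id[1L] else NA
  sched <- data.frame(
    patient_id = patient, week = week, datetime = datetime, slot = slot,
    message_id = ids[slot], rule_id = rule_ids[slot],
    stringsAsFactors = FALSE
  )
  class(sched) <- c("message_schedule", class(sched))
  sched
}

#' Re-tailor messages after the mid-study assessment
#'
#' The tailoring assessment is administered at baseline and again at 4
#' weeks; the week-5 to week-8 schedule is rebuilt from scratch against
#' the week-4 responses, so a barrier resolved by week 4 stops generating
#' messages and a newly failed knowledge item starts.
#'
#' @param week4_responses Response sheet at the 4-week assessment.
#' @param rules Rule list.
#' @param start Original schedule start date (weeks 5-8 begin 28 days
#'   later).
#' @param weeks Number of remaining weeks (default 4).
#' @param preference,rate,general_pool Passed to [schedule_messages()].
#' @return List with `triggered` (fired rules at week 4) and `schedule`
#'   (the rebuilt second-half schedule).
#' @export
retailor <- function(week4_responses, rules = default_message_rules(),
                     start, weeks = 4L,
                     preference = list(weekday = 1L, time = "10:00"),
                     rate = 4L, general_pool = character(0)) {
  triggered <- evaluate_rules(week4_responses, rules)
  schedule <- schedule_messages(triggered, as.Date(start) + 28L, weeks,
                                preference, rate, general_pool)
  list(triggered = triggered, schedule = schedule)
}
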