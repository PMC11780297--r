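rules <- default_message_rules()

sheet <- function(values, options = NULL) {
  items <- c("benefits_medication_01", "barriers_medication_01",
             "barriers_diet_01", "barriers_self_monitoring_01",
             "scse_01")
  df <- data.frame(patient_id = "P1", visit = "baseline",
                   item_id = c(items, "dhfks_01"),
                   value = c(values, NA),
                   chosen_option = c(rep(NA_character_, 5),
                                     options %||% NA_character_),
                   stringsAsFactors = FALSE)
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("benefit rules fire at or below 3, barrier rules at or above 3", {
  # exhaustive truth table over the 5-point response range
  for (v in 1:5) {
    fired <- evaluate_rules(sheet(c(v, v, v, v, v)), rules)
    benefit_fired <- "med_benefit_waterpills" %in% fired$rule_id
    barrier_fired <- all(c("med_barrier_away_from_home",
                           "diet_barrier_taste",
                           "selfmon_barrier_weighing") %in% fired$rule_id)
    efficacy_fired <- "efficacy_confidence_stable" %in% fired$rule_id
    expect_equal(benefit_fired, v <= 3)
    expect_equal(barrier_fired, v >= 3)
    expect_equal(efficacy_fired, v <= 3)
  }
  # at exactly 3 both polarities fire
  fired3 <- evaluate_rules(sheet(rep(3, 5)), rules)
  expect_length(setdiff(c("med_benefit_waterpills",
                          "med_barrier_away_from_home"), fired3$rule_id), 0)
})

test_that("knowledge rules fire on incorrect options only", {
  resp <- sheet(rep(5, 5), options = "call_doctor_or_nurse")
  expect_false("knowledge_breathless_action" %in%
                 evaluate_rules(resp, rules)$rule_id)
  resp$chosen_option[6] <- "take_more_water_pills"
  fired <- evaluate_rules(resp, rules)
  expect_true("knowledge_breathless_action" %in% fired$rule_id)
  expect_equal(fired$reason[fired$rule_id == "knowledge_breathless_action"],
               "take_more_water_pills")
})

test_that("missing answers skip the rule and are logged", {
  resp <- sheet(c(NA, 5, 1, 1, 5))
  fired <- evaluate_rules(resp, rules)
  expect_false("med_benefit_waterpills" %in% fired$rule_id)
  expect_true("med_benefit_waterpills" %in% attr(fired, "skipped"))
  expect_true("dhfks_01" %in% resp$item_id)  # unanswered knowledge item
  expect_true("knowledge_breathless_action" %in% attr(fired, "skipped"))
})

test_that("monotonicity: raising a benefit answer never adds a fired rule", {
  for (v in 1:4) {
    lo <- evaluate_rules(sheet(c(v, 1, 1, 1, 5)), rules)$rule_id
    hi <- evaluate_rules(sheet(c(v + 1, 1, 1, 1, 5)), rules)$rule_id
    expect_true(all(hi %in% lo))
    lo_b <- evaluate_rules(sheet(c(5, v, 1, 1, 5)), rules)$rule_id
    hi_b <- evaluate_rules(sheet(c(5, v + 1, 1, 1, 5)), rules)$rule_id
    expect_true(all(lo_b %in% hi_b))
  }
})

test_that("multi-message sequences are emitted in listed order", {
  fired <- evaluate_rules(sheet(c(5, 1, 1, 1, 2)), rules)
  eff <- fired[fired$rule_id == "efficacy_confidence_stable", ]
  expect_equal(eff$message_id, c("msg_efficacy_1", "msg_efficacy_2"))
  expect_equal(eff$seq, 1:2)
  sched <- schedule_messages(fired, as.Date("2024-01-01"), weeks = 2)
  pos <- match(c("msg_efficacy_1", "msg_efficacy_2"), sched$message_id)
  expect_equal(diff(pos), 1)
})

test_that("schedules deliver 4 per week until exhausted, then the pool", {
  fired <- evaluate_rules(sheet(rep(3, 5),
                                options = "wrong_answer"), rules)
  # at 3 everything fires: 1 benefit + 3 barriers + 2-message efficacy
  # sequence + 1 knowledge = 7 messages
  expect_equal(nrow(fired), 7)
  sched <- schedule_messages(fired, as.Date("2024-01-01"), weeks = 2)
  expect_equal(as.integer(table(sched$week)), c(4L, 3L))
  # exact round-robin: first four slots hit four distinct targets
  first_targets <- fired$target[match(sched$message_id[1:4],
                                      fired$message_id)]
  expect_equal(length(unique(first_targets)), 4)

  pool <- paste0("g", 1:4)
  two <- fired[fired$rule_id == "efficacy_confidence_stable", ]
  s2 <- schedule_messages(two, as.Date("2024-01-01"), weeks = 4,
                          general_pool = pool)
  expect_equal(nrow(s2), 16)
  expect_equal(sum(s2$rule_id == "general_pool"), 14)
  expect_equal(s2$message_id[1:2], c("msg_efficacy_1", "msg_efficacy_2"))
  # zero triggered: whole schedule from the pool
  s0 <- schedule_messages(fired[0, ], as.Date("2024-01-01"), weeks = 1,
                          general_pool = pool)
  expect_equal(s0$message_id, pool)
})

test_that("schedule honors the preferred weekday and is deterministic", {
  fired <- evaluate_rules(sheet(rep(1, 5)), rules)
  pref <- list(weekday = 3L, time = "18:30")  # Wednesdays
  s1 <- schedule_messages(fired, as.Date("2024-01-01"), weeks = 2, pref)
  s2 <- schedule_messages(fired, as.Date("2024-01-01"), weeks = 2, pref)
  expect_identical(s1, s2)
  expect_true(all(format(s1$datetime, "%u") == "3"))
  expect_true(all(format(s1$datetime, "%H:%M") == "18:30"))
  expect_true(all(diff(unique(as.Date(s1$datetime))) == 7))
})

test_that("every scheduled tailored message traces back to one fired rule", {
  fired <- evaluate_rules(sheet(c(2, 4, 3, 5, 1),
                                options = "wrong"), rules)
  sched <- schedule_messages(fired, as.Date("2024-01-01"), weeks = 4,
                             general_pool = "filler")
  tailored <- sched[sched$rule_id != "general_pool", ]
  key_s <- paste(tailored$rule_id, tailored$message_id)
  key_f <- paste(fired$rule_id, fired$message_id)
  expect_setequal(key_s, key_f)
  expect_false(anyDuplicated(key_s) > 0)
  for (i in seq_len(nrow(tailored))) {
    r <- fired[fired$rule_id == tailored$rule_id[i], ]
    expect_true(nrow(r) >= 1)
  }
})

test_that("retailoring rebuilds weeks 5-8 from the week-4 responses", {
  rules1 <- rules
  base <- sheet(c(5, 4, 1, 1, 5))   # barrier fired at baseline
  wk4 <- sheet(c(5, 2, 1, 1, 5))    # barrier resolved at week 4
  wk4$visit <- "week4"
  fired_base <- evaluate_rules(base, rules1)
  expect_true("med_barrier_away_from_home" %in% fired_base$rule_id)
  rt <- retailor(wk4, rules1, start = as.Date("2024-01-01"))
  expect_false("med_barrier_away_from_home" %in% rt$triggered$rule_id)
  expect_true(all(as.Date(rt$schedule$datetime) >=
                    as.Date("2024-01-01") + 28))
  # unchanged answers reproduce the fired set
  same <- retailor(base, rules1, start = as.Date("2024-01-01"))
  expect_equal(same$triggered$rule_id, fired_base$rule_id)
  # knowledge corrected at week 4 drops the education message
  wrong <- sheet(rep(5, 5), options = "wrong")
  right <- sheet(rep(5, 5), options = "call_doctor_or_nurse")
  expect_true("knowledge_breathless_action" %in%
                evaluate_rules(wrong, rules1)$rule_id)
  expect_false("knowledge_breathless_action" %in%
                 retailor(right, rules1,
                          start = as.Date("2024-01-01"))$triggered$rule_id)
})

test_that("the shipped message bank covers every rule's messages", {
  bank <- load_message_bank()
  needed <- unique(unlist(lapply(rules, function(r) r$message_ids)))
  expect_true(all(needed %in% names(bank$messages)))
  expect_true(all(bank$general_pool %in% names(bank$messages)))
})
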