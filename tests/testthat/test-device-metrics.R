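test_that("wear time counts minutes with a heart-rate value", {
  day <- data.frame(heart_rate = c(rep(70, 612), rep(NA, 828)))
  expect_equal(wear_minutes(day), 612L)
  expect_equal(wear_minutes(day[0, , drop = FALSE]), 0L)
  expect_equal(wear_minutes(data.frame(heart_rate = rep(65, 1440))), 1440L)
})

test_that("valid days need at least 600 wear minutes", {
  expect_equal(valid_day(c(600, 599, 1440, 0)),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_error(valid_day(1441), "1440")
})

test_that("weekly summaries use valid days only and drop sparse weeks", {
  start <- as.Date("2024-01-01")
  mk_day <- function(offset, wear, steps) {
    data.frame(patient_id = "P1", date = start + offset, wear_min = wear,
               steps = steps, mvpa_min = 10, sedentary_min = 400)
  }
  days <- rbind(
    # week 1: only 2 valid days -> excluded at min_valid_days = 3
    mk_day(0, 700, 4000), mk_day(1, 650, 6000), mk_day(2, 100, 100),
    mk_day(3, 0, 0), mk_day(4, 0, 0), mk_day(5, 0, 0), mk_day(6, 0, 0),
    # week 2: 3 valid days (4000, 6000, 8000) plus invalid noise
    mk_day(7, 700, 4000), mk_day(8, 650, 6000), mk_day(9, 900, 8000),
    mk_day(10, 10, 50), mk_day(11, 0, 0), mk_day(12, 0, 0),
    mk_day(13, 599, 12000),
    # week 3: 7 constant valid days
    do.call(rbind, lapply(14:20, function(o) mk_day(o, 800, 5000)))
  )
  wk <- weekly_activity_summary(days, start = start, min_valid_days = 3)
  expect_equal(nrow(wk), 3)
  expect_false(wk$valid_week[1])
  expect_true(is.na(wk$mean_steps[1]))
  expect_equal(wk$mean_steps[2], 6000)
  expect_equal(wk$mean_steps[3], 5000)
  expect_equal(wk$n_valid_days, c(2L, 3L, 7L))
  # the stricter 4-valid-day convention drops week 2 as well
  wk4 <- weekly_activity_summary(days, start = start, min_valid_days = 4)
  expect_false(wk4$valid_week[2])
})

test_that("weekly means equal brute-force means from minute streams", {
  set.seed(5)
  start <- as.Date("2024-03-04")
  spec <- data.frame(offset = 0:6,
                     wear = c(700, 650, 800, 200, 620, 900, 0),
                     steps = c(4000, 6000, 8000, 500, 3000, 7000, 0),
                     mvpa = c(20, 35, 10, 2, 15, 40, 0))
  minutes <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    generate_minute_day("P1", start + spec$offset[i], spec$wear[i],
                        spec$steps[i], spec$mvpa[i])
  }))
  # brute-force daily summaries recomputed from the raw minute stream
  daily <- do.call(rbind, lapply(split(minutes,
                                       as.Date(minutes$datetime)), function(d) {
    data.frame(patient_id = "P1", date = as.Date(d$datetime[1]),
               wear_min = sum(!is.na(d$heart_rate)),
               steps = sum(d$steps),
               mvpa_min = sum(d$intensity %in% c("moderate", "vigorous")))
  }))
  expect_equal(daily$wear_min, spec$wear)
  expect_equal(daily$steps, spec$steps)
  wk <- weekly_activity_summary(daily, start = start, min_valid_days = 3)
  valid <- spec$wear >= 600
  expect_equal(wk$mean_steps, mean(spec$steps[valid]))
  expect_equal(wk$mean_mvpa_min, mean(spec$mvpa[valid]))
  expect_equal(wk$mean_wear_min, mean(spec$wear[valid]))
})

test_that("self-monitoring adherence adjusts for hospital days", {
  start <- as.Date("2024-01-01")
  window <- c(start, start + 55)
  mk <- function(measured_days, hospital_days = integer(0)) {
    data.frame(patient_id = "P1",
               date = start + 0:55,
               weight_kg = ifelse(0:55 %in% measured_days, 80, NA),
               in_hospital = 0:55 %in% hospital_days)
  }
  # 48 measured days, no hospital: 48/56
  a <- self_monitoring_adherence(mk(0:47), "weight", window)
  expect_equal(a$adherence_pct, 100 * 48 / 56, tolerance = 1e-12)
  expect_equal(a$eligible_days, 56L)
  # 6 hospital days (unmeasured), 48 of the remaining 50 measured: 96%
  b <- self_monitoring_adherence(mk(0:47, hospital_days = 50:55),
                                 "weight", window)
  expect_equal(b$eligible_days, 50L)
  expect_equal(b$adherence_pct, 96)
  # complete measurement: 100%, and the weekly series is flat
  c_ <- self_monitoring_adherence(mk(0:55), "weight", window)
  expect_equal(c_$adherence_pct, 100)
  expect_equal(c_$weekly_series$adherence_pct, rep(100, 8))
  # duplicates on a day do not change the percentage
  rec <- mk(0:47)
  dup <- rbind(rec, rec[1:10, ])
  expect_equal(self_monitoring_adherence(dup, "weight",
                                         window)$adherence_pct,
               a$adherence_pct)
  # removing hospital days never decreases adherence
  expect_gte(b$adherence_pct, a$adherence_pct)
  # empty window after hospital adjustment is undefined
  e <- self_monitoring_adherence(mk(0:5, hospital_days = 0:5), "weight",
                                 c(start, start + 5))
  expect_true(is.na(e$adherence_pct))
})

test_that("blood-pressure readings map to guideline categories", {
  cases <- data.frame(
    sys = c(118, 124, 125, 135, 150, 179, 185, 121, 140, 130),
    dia = c(78, 79, 85, 82, 95, 119, 125, 92, 80, 79),
    cat = c("normal", "elevated", "stage1", "stage1", "stage2", "stage2",
            "crisis", "stage2", "stage2", "stage1")
  )
  res <- classify_bp(cases$sys, cases$dia)
  expect_equal(as.character(res$category), cases$cat)
  expect_equal(res$emergency,
               cases$sys > 180 | cases$dia > 110)
  expect_error(classify_bp(80, 90), "systolic must exceed")
  expect_error(classify_bp(-120, -80), "positive")
})

test_that("every valid reading falls in exactly one category", {
  grid <- expand.grid(sys = seq(90, 220, by = 1),
                      dia = seq(50, 130, by = 1))
  grid <- grid[grid$sys > grid$dia, ]
  res <- classify_bp(grid$sys, grid$dia)
  expect_false(anyNA(res$category))
  # spot-check the band edges against the written definition
  band <- function(s, d) as.character(classify_bp(s, d)$category)
  expect_equal(band(119, 79), "normal")
  expect_equal(band(120, 79), "elevated")
  expect_equal(band(129, 79), "elevated")
  expect_equal(band(130, 79), "stage1")
  expect_equal(band(139, 89), "stage1")
  expect_equal(band(140, 90), "stage2")
  expect_equal(band(180, 120), "crisis")
})

test_that("weight alerts flag day-over-day gains at the 3-pound rule", {
  s <- data.frame(date = as.Date("2024-01-01") + 0:3,
                  weight_kg = c(100, 101.4, 101.4, 101.4))
  r <- weight_change_alert(s)
  expect_equal(r$alert, c(FALSE, TRUE, FALSE, FALSE))
  # constant weight never alerts
  flat <- data.frame(date = as.Date("2024-01-01") + 0:5, weight_kg = 90)
  expect_false(any(weight_change_alert(flat)$alert))
  # +2.2 kg across a 3-day gap: no daily alert, cumulative change shown
  gap <- data.frame(date = as.Date("2024-01-01") + c(0, 3),
                    weight_kg = c(100, 102.2))
  g <- weight_change_alert(gap)
  expect_false(any(g$alert, na.rm = TRUE))
  expect_equal(g$change_since_last[2], 2.2)
  expect_equal(g$days_since_last[2], 3L)
})
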