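# Meal bands, bolus classification, mealtime imputation and 4-hour
# window isolation.

test_that("clock times map to half-open meal bands", {
  expect_equal(band_of("07:30"), "breakfast")
  expect_equal(band_of("06:00"), "breakfast")
  expect_equal(band_of("10:00"), "lunch")   # left-closed boundary
  expect_equal(band_of("14:00"), "snack")
  expect_equal(band_of("18:00"), "dinner")
  expect_true(is.na(band_of("22:00")))
  expect_true(is.na(band_of("23:00")))
  expect_true(is.na(band_of("05:59")))
  expect_equal(band_of(ts_utc("2021-06-07 12:30:00")), "lunch")
})

test_that("boluses classify by the -4 min / +4 h meal window", {
  meals <- data.frame(timestamp = ts_utc("2021-06-07 12:00:00"),
                      carbs = 50, source = "reported")
  bts <- ts_utc("2021-06-07 12:00:00") +
    60 * c(-3, -5, 239, 240, 241, -4)
  rec <- make_record(glucose = flat_glucose_day(), meals = meals,
                     boluses = data.frame(timestamp = bts, dose = 2,
                                          kind = "unclassified"))
  rec <- classify_boluses(rec)
  kinds <- rec$boluses$kind[order(rec$boluses$timestamp)]
  # sorted: -5, -4, -3, +239, +240, +241 minutes
  expect_equal(kinds, c("correction", "meal_related", "meal_related",
                        "meal_related", "meal_related", "correction"))
  expect_equal(classify_boluses(rec)$boluses$kind, rec$boluses$kind)
})

test_that("mealtimes impute from same-weekday bands in other weeks", {
  mondays <- ts_utc("2021-06-07 12:00:00") + 7 * 86400 * c(0, 1, 3)
  meals <- data.frame(timestamp = mondays + 600 * c(0, 1, 2),  # 12:00/:10/:20
                      carbs = 50, source = "reported")
  # span must cover week 3's Monday; anchor with sparse glucose
  g <- data.frame(timestamp = ts_utc("2021-06-07 00:00:00") +
                    c(0, 27 * 86400), value = 6)
  rec <- make_record(glucose = g, meals = meals)
  imp <- impute_start_times(rec)
  expect_equal(nrow(imp), 1)
  expect_equal(imp$timestamp, ts_utc("2021-06-21 12:10:00"))
  expect_true(is.na(imp$carbs))
  expect_equal(imp$source, "imputed")

  # a band-day already holding a reported meal is never imputed
  rec2 <- rec
  rec2$meals <- rbind(rec2$meals,
                      data.frame(timestamp = ts_utc("2021-06-21 12:05:00"),
                                 carbs = 10, source = "reported"))
  expect_equal(nrow(impute_start_times(make_record(
    glucose = g, meals = rec2$meals))), 0)

  # single-week records have no "other weeks"
  rec3 <- make_record(glucose = flat_glucose_day(),
                      meals = meals[1, , drop = FALSE])
  expect_equal(nrow(impute_start_times(rec3)), 0)
})

test_that("a meal-related bolus blocks imputation for its band-day", {
  mondays <- ts_utc("2021-06-07 12:00:00") + 7 * 86400 * c(0, 1, 3)
  meals <- data.frame(timestamp = mondays, carbs = 50, source = "reported")
  g <- data.frame(timestamp = ts_utc("2021-06-07 00:00:00") +
                    c(0, 27 * 86400), value = 6)
  # week-3 Monday: no lunch meal, but a 13:58 bolus that is meal-related
  # (2 min before a 14:00 snack-band meal) sits in the lunch band and
  # blocks lunch imputation for that day
  meals2 <- rbind(meals, data.frame(
    timestamp = ts_utc("2021-06-21 14:00:00"), carbs = 20,
    source = "reported"))
  bol <- data.frame(timestamp = ts_utc("2021-06-21 13:58:00"),
                    dose = 2, kind = "unclassified")
  rec <- make_record(glucose = g, meals = meals2, boluses = bol)
  imp <- impute_start_times(rec)
  expect_false(any(band_of(imp$timestamp) == "lunch" &
                     as.Date(imp$timestamp) == as.Date("2021-06-21")))
})

test_that("gap-free windows isolate 48 samples; short windows are excluded", {
  meals <- data.frame(timestamp = ts_utc("2021-06-07 08:00:00"),
                      carbs = 45, source = "reported")
  rec <- make_record(glucose = flat_glucose_day(), meals = meals)
  iso <- isolate_ppgrs(rec)
  expect_equal(nrow(iso$events), 1)
  expect_equal(iso$events$n_points, 48L)
  expect_equal(iso$report$isolated + iso$report$excluded,
               iso$report$candidates)

  # 24 in-window samples: retained; 23: excluded
  g24 <- flat_glucose_day()
  keep24 <- g24$timestamp >= ts_utc("2021-06-07 08:00:00") &
    g24$timestamp < ts_utc("2021-06-07 10:00:00")
  rec24 <- make_record(glucose = g24[keep24, ], meals = meals)
  iso24 <- isolate_ppgrs(rec24)
  expect_equal(iso24$events$n_points, 24L)

  rec23 <- make_record(glucose = g24[keep24, ][-1, ], meals = meals)
  iso23 <- isolate_ppgrs(rec23)
  expect_equal(nrow(iso23$events), 0)
  expect_equal(iso23$report$excluded, 1L)
})

test_that("same-band intakes inside the window merge their carbs", {
  meals <- data.frame(
    timestamp = ts_utc(c("2021-06-07 08:00:00", "2021-06-07 08:30:00")),
    carbs = c(60, 20), source = "reported")
  rec <- make_record(glucose = flat_glucose_day(), meals = meals)
  iso <- isolate_ppgrs(rec)
  expect_equal(nrow(iso$events), 1)
  expect_equal(iso$events$carbs_total, 80)
  expect_equal(iso$report$merged_intakes, 1L)

  # a different-band meal inside the window starts its own event
  meals2 <- data.frame(
    timestamp = ts_utc(c("2021-06-07 08:30:00", "2021-06-07 10:30:00")),
    carbs = c(60, 40), source = "reported")
  iso2 <- isolate_ppgrs(make_record(glucose = flat_glucose_day(),
                                    meals = meals2))
  expect_equal(sort(iso2$events$band), c("breakfast", "lunch"))
  expect_equal(iso2$events$carbs_total[iso2$events$band == "breakfast"], 60)
})

test_that("candidate dedup prefers reported meal > bolus > imputed", {
  meals <- data.frame(timestamp = ts_utc("2021-06-07 08:10:00"),
                      carbs = 30, source = "reported")
  bol <- data.frame(timestamp = ts_utc("2021-06-07 08:05:00"),
                    dose = 3, kind = "unclassified")
  rec <- classify_boluses(make_record(glucose = flat_glucose_day(),
                                      meals = meals, boluses = bol))
  iso <- isolate_ppgrs(rec)
  expect_equal(nrow(iso$events), 1)
  expect_equal(iso$events$origin, "reported_meal")

  # bolus alone in a band-day seeds a mealtime-bolus event
  rec2 <- make_record(glucose = flat_glucose_day(),
                      meals = data.frame(
                        timestamp = ts_utc("2021-06-07 12:30:00"),
                        carbs = 50, source = "reported"),
                      boluses = data.frame(
                        timestamp = ts_utc("2021-06-07 12:32:00"),
                        dose = 4, kind = "unclassified"))
  rec2 <- classify_boluses(rec2)
  # lunch bolus is meal_related and its band-day has a meal: no extra event
  iso2 <- isolate_ppgrs(rec2)
  expect_equal(nrow(iso2$events), 1)
  expect_equal(iso2$events$origin, "reported_meal")
})

test_that("peak normalization subtracts the window maximum", {
  expect_equal(peak_normalize(c(7, 9.5, 8)), c(-2.5, 0, -1.5))
  expect_equal(peak_normalize(c(6, 6, 6)), c(0, 0, 0))
  set.seed(21)
  for (i in 1:20) {
    v <- runif(sample(5:48, 1), 3, 15)
    expect_identical(max(peak_normalize(v)), 0)
  }
  expect_error(peak_normalize(numeric()), "empty")
})

test_that("isolation is order-invariant and respects window invariants", {
  res <- simulate_participant(sim_config(weeks = 2, seed = 99,
                                         p_sensor_dropout = 0.3), 1)
  rec <- with_imputed_meals(res$record)
  iso <- isolate_ppgrs(rec)
  ev <- iso$events
  expect_true(all(ev$n_points >= 24 & ev$n_points <= 48))
  expect_true(all(!is.na(ev$band)))
  expect_true(all(vapply(ev$normalized,
                         function(v) max(v, na.rm = TRUE) == 0,
                         logical(1))))
  expect_true(all(band_of(ev$start) == ev$band))

  shuf <- rec
  set.seed(1)
  shuf$meals <- shuf$meals[sample(nrow(shuf$meals)), , drop = FALSE]
  shuf$boluses <- shuf$boluses[sample(nrow(shuf$boluses)), , drop = FALSE]
  shuf$glucose <- shuf$glucose[sample(nrow(shuf$glucose)), , drop = FALSE]
  shuf <- make_record("S01", glucose = shuf$glucose, meals = shuf$meals,
                      boluses = shuf$boluses)
  shuf$boluses$kind <- "unclassified"
  shuf <- with_imputed_meals(shuf)
  iso2 <- isolate_ppgrs(shuf)
  expect_equal(iso2$events$event_id, ev$event_id)
  expect_equal(iso2$events$glucose, ev$glucose)
})

test_that("empty glucose series yields an empty result, not an error", {
  rec <- make_record(glucose = data.frame(timestamp = ts_utc(character()),
                                          value = numeric()),
                     meals = data.frame(
                       timestamp = ts_utc("2021-06-07 08:00:00"),
                       carbs = 30, source = "reported"))
  iso <- isolate_ppgrs(rec)
  expect_equal(nrow(iso$events), 0)
})

test_that("gap-free records emit one event per logged band-day", {
  cfg <- sim_config(weeks = 2, seed = 5, noise_sd = 0.1,
                    p_missing_mealtime = 0, p_sensor_dropout = 0)
  res <- simulate_participant(cfg, 1)
  iso <- isolate_ppgrs(classify_boluses(res$record))
  expect_equal(nrow(iso$events), nrow(res$truth))  # 14 days x 3 bands
  expect_equal(iso$report$excluded, 0L)
})
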