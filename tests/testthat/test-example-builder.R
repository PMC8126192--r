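test_that("time-of-day windows have the five standard boundaries", {
  expect_equal(tod_interval("07:30"), 2)
  expect_equal(tod_interval("00:00"), 1)
  expect_equal(tod_interval("18:00"), 5)
  expect_equal(tod_interval(c(0, 360, 600, 840, 1080) ), c(1, 2, 3, 4, 5))
  expect_equal(tod_interval(c(359, 599, 839, 1079, 1439)), c(1, 2, 3, 4, 5))
  expect_equal(tod_interval("12:15"), 3)
})

test_that("meals are classified by the presence of a bolus 10 minutes before", {
  rec <- flat_record(2000,
                     boluses = data.frame(time = c(590, 1000), dose = c(4, 1.5),
                                          bw_carb_input = c(45, NA)),
                     meals = data.frame(time = c(600, 1500, 1045), carbs = c(45, 20, 30)))
  expect_equal(classify_meal(600, rec), "with_bolus")     # anchored meal
  expect_equal(classify_meal(1500, rec), "without_bolus") # snack, no bolus at all
  expect_equal(classify_meal(1045, rec), "without_bolus") # correction bolus 45 min earlier
})

test_that("inertial windows admit only the queried event (and its paired meal)", {
  rec <- flat_record(3000,
                     boluses = data.frame(time = 1010, dose = 5, bw_carb_input = 50),
                     meals = data.frame(time = 1020, carbs = 50))
  # bolus at t+10 with its meal at t+20: inertial for bolus-given-carbs only
  expect_true(is_inertial(1010, 60, "bolus_p_c", rec))
  expect_false(is_inertial(1010, 60, "bolus_pm_c", rec))
  # a snack at t+40 blocks every scenario
  rec2 <- rec
  rec2$meals <- rbind(rec2$meals, data.frame(time = 1040, carbs = 15,
                                             source = "smartphone",
                                             shifted = FALSE, added = FALSE))
  for (sc in SCENARIOS) expect_false(is_inertial(1010, 60, sc, rec2))
  # carb event with no bolus in the window is inertial for carb scenarios
  rec3 <- flat_record(3000, meals = data.frame(time = 1020, carbs = 20))
  expect_true(is_inertial(1020, 60, "carbs_m_b", rec3))
})

test_that("a fully covered event yields one example per horizon on the tau grid", {
  rec <- flat_record(2875,
                     meals = data.frame(time = c(600, 2000), carbs = c(30, 55)),
                     split = c(1000, 1500))
  ex <- build_examples(rec, "carbs_pm_b", "unrestricted")
  got <- ex$meta[ex$meta$event_time == 2000, ]
  expect_equal(nrow(got), 13)
  expect_equal(got$tau, seq(30, 90, 5))
  expect_equal(unique(got$label), 55)          # all 13 share the label
  expect_equal(unique(got$target_bg), 120)
  # rows differ only in (tau, target_bg): all other fields constant
  expect_equal(nrow(unique(got[, c("event_time", "t", "tod_avg", "label")])), 1)
})

test_that("horizons past the record end are dropped (enumeration oracle)", {
  end <- 2875
  te <- 2795
  rec <- flat_record(end,
                     meals = data.frame(time = c(600, te), carbs = c(30, 55)),
                     split = c(1000, 1500))
  ex <- build_examples(rec, "carbs_pm_b", "unrestricted")
  got <- ex$meta[ex$meta$event_time == te, ]
  expected_taus <- Filter(function(tau) te + tau <= end, seq(30, 90, 5))
  expect_equal(got$tau, as.numeric(expected_taus))
  expect_lt(nrow(got), 13)
})

test_that("dual boluses are never prediction labels", {
  rec <- flat_record(2875,
                     boluses = data.frame(time = c(600, 2000), dose = c(4, 6),
                                          kind = c("normal", "dual"),
                                          bw_carb_input = c(NA, NA)),
                     split = c(1000, 1500))
  ex <- build_examples(rec, "bolus_pm_c", "unrestricted")
  expect_false(any(ex$meta$event_time == 2000))
  expect_true(any(ex$meta$event_time == 600))
})

test_that("unanchored records are rejected unless the ablation is explicit", {
  rec <- flat_record(2875, meals = data.frame(time = c(600, 2000), carbs = c(30, 55)),
                     split = c(1000, 1500))
  rec$anchored <- FALSE
  expect_error(build_examples(rec, "carbs_pm_b", "unrestricted"), "anchor")
  expect_s3_class(build_examples(rec, "carbs_pm_b", "unrestricted", allow_raw = TRUE),
                  "rec_examples")
})

test_that("inertial examples are a subset of unrestricted examples", {
  rec <- interpolate_glucose(anchor_meals(sim_fixture(seed = 31, days = 23)))
  rec$split <- c(8 * 1440, 15 * 1440)
  for (sc in c("carbs_pm_b", "bolus_p_c")) {
    iner <- build_examples(rec, sc, "inertial")
    unre <- build_examples(rec, sc, "unrestricted")
    key <- function(m) paste(m$event_time, m$tau)
    expect_true(all(key(iner$meta) %in% key(unre$meta)))
    expect_lte(nrow(iner$meta), nrow(unre$meta))
  }
  # meal populations of the two carb scenarios are nested and consistent
  mb <- build_examples(rec, "carbs_m_b", "unrestricted")
  pm <- build_examples(rec, "carbs_pm_b", "unrestricted")
  expect_true(all(mb$meta$event_time %in% pm$meta$event_time))
  with_b <- vapply(unique(mb$meta$event_time),
                   function(tt) classify_meal(tt, rec), "")
  expect_true(all(with_b == "without_bolus"))
})

test_that("the queried event never leaks into the input channels", {
  rec <- interpolate_glucose(anchor_meals(sim_fixture(seed = 31, days = 23)))
  rec$split <- c(8 * 1440, 15 * 1440)
  ex <- build_examples(rec, "bolus_p_c", "inertial")
  for (j in seq_len(min(nrow(ex$meta), 40))) {
    W <- ex$window[[j]]
    expect_lt(max(abs(W[, "bolus"])), 1e-9)   # only the queried bolus was there
    expect_lt(max(abs(W[, "carbs"])), 1e-9)   # only its paired meal was there
  }
  exm <- build_examples(rec, "carbs_m_b", "inertial")
  for (j in seq_len(min(nrow(exm$meta), 40)))
    expect_lt(max(abs(exm$window[[j]][, "carbs"])), 1e-9)
})

test_that("the time-of-day feature comes from the training split only", {
  rec <- flat_record(2875,
                     meals = data.frame(time = c(600, 620, 2000), carbs = c(30, 40, 90)),
                     split = c(1000, 1500))
  ex <- build_examples(rec, "carbs_pm_b", "unrestricted")
  # training meals (both at 10:00-10:20, window 3) average to 35; the 90 g
  # test meal must not contaminate the feature
  got <- ex$meta[ex$meta$event_time == 2000, ]
  expect_equal(unique(got$tod_avg), 35)
})

test_that("eligibility report counts qualifying events per split", {
  recs <- lapply(c(31, 32), function(s) {
    r <- anchor_meals(sim_fixture(seed = s, days = 23))
    split_record(r)
  })
  rep <- eligibility_report(recs, "carbs_pm_b", min_events = 1)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$train > 0))
  expect_true(all(c("validation", "test", "eligible") %in% names(rep)))
  strict <- eligibility_report(recs, "carbs_m_b", min_events = 10000)
  expect_false(any(strict$eligible))
})
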