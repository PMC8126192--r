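test_that("a bolus claims the closest smartphone meal and re-times it to +10", {
  rec <- flat_record(2000,
                     boluses = data.frame(time = 600, dose = 5, bw_carb_input = 45),
                     meals = data.frame(time = 580, carbs = 40))
  out <- anchor_meals(rec)
  expect_equal(nrow(out$meals), 1)
  expect_equal(out$meals$time, 610)
  expect_equal(out$meals$carbs, 45)        # bolus-wizard grams replace the estimate
  expect_true(out$meals$shifted)
  expect_false(out$meals$added)
  expect_equal(out$meals$orig_time, 580)   # provenance retained
  expect_equal(out$meals$orig_carbs, 40)
})

test_that("a meal is created when none is logged within the matching window", {
  rec <- flat_record(2000,
                     boluses = data.frame(time = 600, dose = 3, bw_carb_input = 30),
                     meals = data.frame(time = 661, carbs = 35))  # 61 min away
  out <- anchor_meals(rec)
  added <- out$meals[out$meals$added, ]
  expect_equal(nrow(added), 1)
  expect_equal(added$time, 610)
  expect_equal(added$carbs, 30)
  expect_equal(added$source, "bolus_wizard")
  # the distant meal is untouched
  expect_true(any(out$meals$time == 661 & !out$meals$shifted))
})

test_that("distance ties break on carb closeness, then on the earlier meal", {
  rec <- flat_record(2000,
                     boluses = data.frame(time = 600, dose = 5, bw_carb_input = 45),
                     meals = data.frame(time = c(580, 620), carbs = c(25, 44)))
  out <- anchor_meals(rec)
  shifted <- out$meals[out$meals$shifted, ]
  expect_equal(shifted$orig_carbs, 44)     # 44 g closer to the 45 g BW entry
  rec2 <- flat_record(2000,
                      boluses = data.frame(time = 600, dose = 5, bw_carb_input = 45),
                      meals = data.frame(time = c(580, 620), carbs = c(44, 44)))
  out2 <- anchor_meals(rec2)
  expect_equal(out2$meals$orig_time[out2$meals$shifted], 580)  # earlier wins
})

test_that("anchoring establishes the bolus-to-meal bijection and is idempotent", {
  rec <- sim_fixture(seed = 21, days = 23)
  out <- anchor_meals(rec)
  bw <- out$boluses[!is.na(out$boluses$bw_carb_input) & out$boluses$bw_carb_input > 0, ]
  for (i in seq_len(nrow(bw))) {
    hit <- out$meals$time == bw$time[i] + 10 & out$meals$carbs == bw$bw_carb_input[i]
    expect_equal(sum(hit), 1)
  }
  twice <- anchor_meals(out)
  expect_equal(twice$meals[, c("time", "carbs", "shifted", "added")],
               out$meals[, c("time", "carbs", "shifted", "added")])
  expect_error(anchor_meals(flat_record(100, boluses = data.frame(
    time = 50, dose = 1, bw_carb_input = -5))), "negative")
})

test_that("glucose gaps are filled linearly, interior only, measured kept exact", {
  rec <- subject_record("s", data.frame(time = c(0, 20), value = c(100, 120)))
  out <- interpolate_glucose(rec)
  expect_equal(out$glucose$time, seq(0, 20, 5))
  expect_equal(out$glucose$value, c(100, 105, 110, 115, 120))
  expect_equal(out$glucose$interpolated, c(FALSE, TRUE, TRUE, TRUE, FALSE))

  full <- subject_record("s", data.frame(time = seq(0, 30, 5), value = 100 + 0:6))
  expect_equal(interpolate_glucose(full)$glucose$value, full$glucose$value)
  expect_false(any(interpolate_glucose(full)$glucose$interpolated))

  # nothing extrapolated past the last measurement
  tail_gap <- subject_record("s", data.frame(time = c(0, 5, 10), value = c(100, 101, 102)))
  tail_gap$basal <- data.frame(start = 0, end = 60, rate = 1)
  expect_equal(max(interpolate_glucose(tail_gap)$glucose$time), 10)
  expect_error(interpolate_glucose(subject_record("s", data.frame(time = 0, value = 90))),
               "at least 2")
})

test_that("interpolation fills monotone gaps monotonically", {
  rec <- subject_record("s", data.frame(time = c(0, 60, 65, 200), value = c(80, 140, 141, 190)))
  out <- interpolate_glucose(rec)
  expect_true(all(diff(out$glucose$value) >= 0))
  meas <- rec$glucose
  expect_equal(out$glucose$value[match(meas$time, out$glucose$time)], meas$value)
})

test_that("admissibility filters fire exactly at their boundaries", {
  base <- flat_record(800)
  t <- 500
  # 12 interpolated in (t-360, t], none in (t-60, t]: admissible; 13: not
  mk <- function(n_six, n_hour) {
    r <- base
    idx_six <- which(r$glucose$time > t - 360 & r$glucose$time <= t - 60)
    idx_hour <- which(r$glucose$time > t - 60 & r$glucose$time < t)
    r$glucose$interpolated[idx_six[seq_len(n_six)]] <- TRUE
    if (n_hour) r$glucose$interpolated[idx_hour[seq_len(n_hour)]] <- TRUE
    r
  }
  expect_true(is_admissible(t, 30, mk(12, 0)))
  expect_false(is_admissible(t, 30, mk(13, 0)))
  expect_true(is_admissible(t, 30, mk(0, 2)))
  expect_false(is_admissible(t, 30, mk(0, 3)))
  # interpolated target or present sample vetoes on its own
  r <- base; r$glucose$interpolated[r$glucose$time == t + 40] <- TRUE
  expect_false(is_admissible(t, 30, r))
  r <- base; r$glucose$interpolated[r$glucose$time == t] <- TRUE
  expect_false(is_admissible(t, 30, r))
  # horizon beyond the record end
  expect_false(is_admissible(790, 30, base))
  expect_true(is_admissible(t, 30, base))
})

test_that("adding interpolated samples never makes an example admissible", {
  set.seed(42)
  for (rep in 1:20) {
    r <- flat_record(800)
    flips <- sample(nrow(r$glucose), 15)
    r2 <- r
    r2$glucose$interpolated[flips[1:10]] <- TRUE
    r3 <- r2
    r3$glucose$interpolated[flips] <- TRUE
    t <- 5 * sample(80:140, 1)
    if (!is_admissible(t, 30, r2)) expect_false(is_admissible(t, 30, r3))
  }
})

test_that("the scaler maps the training range to [0,1] without clipping", {
  train <- to_grid(flat_record(200, meals = data.frame(time = 50, carbs = 40),
                               boluses = data.frame(time = 100, dose = 4)))
  train$bg <- seq(40, 400, length.out = nrow(train))
  train$basal[1] <- 0   # vary the basal channel so every channel is fittable
  sc <- fit_scaler(train, labels = c(10, 50))
  expect_equal(scale_channel(220, sc, "bg"), 0.5)
  expect_equal(scale_channel(40, sc, "bg"), 0)
  expect_equal(scale_channel(400, sc, "bg"), 1)
  expect_gt(scale_channel(420, sc, "bg"), 1)   # no clipping
  x <- runif(50, 0, 500)
  expect_equal(unscale_channel(scale_channel(x, sc, "bg"), sc, "bg"), x, tolerance = 1e-9)
  flat <- train; flat$basal <- 1
  expect_error(fit_scaler(flat, labels = c(1, 2)), "basal")
})
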