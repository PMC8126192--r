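#' Recommendation scenarios
#'
#' Four event populations are distinguished. `carbs_pm_b` covers all
#' carbohydrate intake events, with or without an associated bolus;
#' `carbs_m_b` only carbohydrate intakes without a bolus (hypo corrections,
#' pre-exercise and bedtime snacks); `bolus_pm_c` all regular boluses; and
#' `bolus_p_c` only boluses followed by a meal 10 minutes later, for which the
#' planned carbohydrate amount is part of the model input. The label channel is
#' carbohydrate grams for the first two and bolus units for the last two.
#'
#' @format character vector of the four scenario codes.
#' @export
SCENARIOS <- c("carbs_pm_b", "carbs_m_b", "bolus_pm_c", "bolus_p_c")

#' Time-of-day interval index
#'
#' The day is partitioned into five windows: 12am-6am (1, early breakfast/late
#' snacks), 6am-10am (2, breakfast), 10am-2pm (3, lunch), 2pm-6pm (4, dinner),
#' 6pm-12am (5, late dinner/post-dinner snacks). Windows are left-closed.
#'
#' @param wall_min minute-of-day in `[0, 1440)`, or a `"HH:MM"` string.
#' @return integer index in 1..5 (vectorised).
#' @export
tod_interval <- function(wall_min) {
  if (is.character(wall_min)) {
    p <- strsplit(wall_min, ":", fixed = TRUE)
    wall_min <- vapply(p, function(x) as.numeric(x[1]) * 60 + as.numeric(x[2]), 0)
  }
  stopifnot(all(wall_min >= 0 & wall_min < 1440))
  findInterval(wall_min, c(0, 360, 600, 840, 1080))
}

#' Does a meal have an associated bolus?
#'
#' After anchoring, a meal covered by a bolus sits exactly 10 minutes after
#' it; classification therefore tests for a bolus at `meal time - 10`.
#'
#' @param meal_time meal timestamp, minutes.
#' @param record an anchored `subject_record`.
#' @return `"with_bolus"` or `"without_bolus"`.
#' @export
classify_meal <- function(meal_time, record) {
  if (any(abs(record$boluses$time - (meal_time - 10)) < 1e-9))
    "with_bolus" else "without_bolus"
}

#' Is a prediction window free of confounding events?
#'
#' An example is inertial when no meal and no bolus falls in the prediction
#' window `(t, t+10+tau]` other than the queried event at `t+10` and, for the
#' bolus-given-carbs scenario only, its paired meal at `t+20`. Inertial
#' examples correspond to the intended use of a recommender: nothing else is
#' planned between now and the target time.
#'
#' @param event_time time of the queried event (`t + 10`), minutes.
#' @param tau horizon, minutes.
#' @param scenario one of [SCENARIOS].
#' @param record a `subject_record`.
#' @return logical.
#' @export
is_inertial <- function(event_time, tau, scenario, record) {
  scenario <- match.arg(scenario, SCENARIOS)
  t <- event_time - 10
  hi <- t + 10 + tau
  mt <- record$meals$time
  bt <- record$boluses$time
  meals_in <- mt[mt > t & mt <= hi]
  bol_in <- bt[bt > t & bt <= hi]
  if (scenario %in% c("carbs_pm_b", "carbs_m_b")) {
    meals_in <- drop_one(meals_in, event_time)
    length(meals_in) == 0 && length(bol_in) == 0
  } else {
    bol_in <- drop_one(bol_in, event_time)
    if (scenario == "bolus_p_c") meals_in <- drop_one(meals_in, event_time + 10)
    length(meals_in) == 0 && length(bol_in) == 0
  }
}

# remove a single occurrence of `value` from x, if present
drop_one <- function(x, value) {
  i <- which(abs(x - value) < 1e-9)
  if (length(i)) x[-i[1]] else x
}

# qualifying events for a scenario: data.frame(time, label, planned_carbs)
scenario_events <- function(record, scenario) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (scenario %in% c("carbs_pm_b", "carbs_m_b")) {
    m <- record$meals
    keep <- rep(TRUE, nrow(m))
    if (scenario == "carbs_m_b")
      keep <- vapply(m$time, function(tt) classify_meal(tt, record) == "without_bolus", TRUE)
    data.frame(time = m$time[keep], label = m$carbs[keep],
               planned_carbs = rep(NA_real_, sum(keep)))
  } else {
    b <- record$boluses
    keep <- b$kind == "normal" & b$dose > 0
    if (scenario == "bolus_p_c") {
      has_meal <- vapply(b$time, function(tt) any(abs(record$meals$time - (tt + 10)) < 1e-9), TRUE)
      keep <- keep & has_meal
    }
    pc <- rep(NA_real_, nrow(b))
    if (scenario == "bolus_p_c") {
      idx <- vapply(b$time, function(tt) {
        i <- which(abs(record$meals$time - (tt + 10)) < 1e-9)
        if (length(i)) i[1] else NA_integer_
      }, 1L)
      pc <- record$meals$carbs[idx]
    }
    data.frame(time = b$time[keep], label = b$dose[keep], planned_carbs = pc[keep])
  }
}

#' Build recommendation examples from a pre-processed record
#'
#' For each qualifying event at time `t+10` (a meal for carbohydrate
#' scenarios; a regular bolus for bolus scenarios; for bolus-given-carbs, a
#' bolus whose anchored meal sits at `t+20`) and each horizon `tau` on the
#' 5-minute grid from 30 to 90 minutes, one example is emitted when the
#' 72-step history exists, the target time `t+10+tau` lies inside the record,
#' the interpolation filters admit the example, and - for the inertial class -
#' the prediction window is free of other events. All 13 horizon variants of
#' one event share the same label (the event magnitude in g or u) and differ
#' in the glucose target and the `tau` feature. Values are stored in physical
#' units; scaling happens at model time.
#'
#' The time-of-day average feature is computed from the subject's training
#' split only (boundary `record$split[1]`), falling back to the subject's
#' global training average for windows without training events.
#'
#' @param record an anchored and interpolated `subject_record` with a `split`.
#' @param scenario one of [SCENARIOS].
#' @param example_class `"inertial"` or `"unrestricted"`.
#' @param taus horizon grid, minutes (default `seq(30, 90, 5)`).
#' @param history_steps lookback length (default 72 steps = 6 h).
#' @param allow_raw build on an un-anchored record (ablation of the meal
#'   anchoring step); off by default to guard against accidental raw builds.
#' @return an object of class `rec_examples`: `meta` (one row per example),
#'   `history` (list of `history_steps x 4` matrices: bg, carbs, bolus, basal)
#'   and `window` (list of `W x 3` matrices: carbs, bolus, basal over
#'   `(t, t+10+tau]`, with the queried event excluded).
#' @export
build_examples <- function(record, scenario, example_class = c("inertial", "unrestricted"),
                           taus = seq(30, 90, by = 5), history_steps = 72,
                           allow_raw = FALSE) {
  scenario <- match.arg(scenario, SCENARIOS)
  example_class <- match.arg(example_class)
  if (!record$anchored && !allow_raw)
    stop("record is not anchored; run anchor_meals() first (or allow_raw = TRUE for the ablation)")
  if (!record$interpolated) stop("record glucose is not interpolated; run interpolate_glucose()")
  if (is.null(record$split)) stop("record has no train/validation split boundaries")
  grid <- to_grid(record)
  bg_at <- function(tt) grid$bg[tt / 5 + 1]
  events <- scenario_events(record, scenario)
  # ToD averages from the training split only
  train_ev <- events[events$time < record$split[1], , drop = FALSE]
  if (nrow(train_ev) == 0) stop("no training-split events for scenario ", scenario)
  tod_k <- tod_interval(wall_minute(record, train_ev$time))
  mu_global <- mean(train_ev$label)
  mu_k <- vapply(1:5, function(k) {
    v <- train_ev$label[tod_k == k]
    if (length(v)) mean(v) else mu_global
  }, 0)

  # fast admissibility on the contiguous interpolated glucose grid
  g <- record$glucose
  g0 <- g$time[1]
  cs <- c(0, cumsum(g$interpolated))
  gi_of <- function(tt) (tt - g0) / 5 + 1
  admissible_fast <- function(t, tau) {
    it <- gi_of(t + 10 + tau)
    i0 <- gi_of(t)
    if (it < 1 || it > nrow(g) || i0 < 1 || i0 > nrow(g)) return(FALSE)
    if (g$interpolated[it] || g$interpolated[i0]) return(FALSE)
    ia <- max(gi_of(t - 60), 0)
    if (cs[i0 + 1] - cs[ia + 1] > 2) return(FALSE)
    ib <- max(gi_of(t - 360), 0)
    cs[i0 + 1] - cs[ib + 1] <= 12
  }

  meta <- list(); hist_l <- list(); win_l <- list()
  first_bg <- min(grid$time[!is.na(grid$bg)])
  last_t <- max(grid$time)
  for (e in seq_len(nrow(events))) {
    te_raw <- events$time[e]
    te <- grid_snap(te_raw)   # raw (un-anchored) meals may sit off-grid
    t <- te - 10
    if (t - 5 * (history_steps - 1) < first_bg || t < 0) next
    wall <- wall_minute(record, te)
    k <- tod_interval(wall)
    for (tau in taus) {
      if (t + 10 + tau > last_t) next
      if (!admissible_fast(t, tau)) next
      if (example_class == "inertial" && !is_inertial(te_raw, tau, scenario, record)) next
      h_times <- seq(t - 5 * (history_steps - 1), t, by = 5)
      hi <- h_times / 5 + 1
      H <- cbind(bg = grid$bg[hi], carbs = grid$carbs[hi],
                 bolus = grid$bolus[hi], basal = grid$basal[hi])
      if (anyNA(H[, "bg"])) next
      w_times <- seq(t + 5, t + 10 + tau, by = 5)
      wi <- w_times / 5 + 1
      W <- cbind(carbs = grid$carbs[wi], bolus = grid$bolus[wi], basal = grid$basal[wi])
      # the queried event never appears in the inputs (no label leakage)
      ebin <- which(w_times == te)
      if (scenario %in% c("carbs_pm_b", "carbs_m_b")) {
        W[ebin, "carbs"] <- W[ebin, "carbs"] - events$label[e]
      } else {
        W[ebin, "bolus"] <- W[ebin, "bolus"] - events$label[e]
        if (scenario == "bolus_p_c") {
          mbin <- which(w_times == grid_snap(te_raw + 10))
          W[mbin, "carbs"] <- W[mbin, "carbs"] - events$planned_carbs[e]
        }
      }
      meta[[length(meta) + 1]] <- data.frame(
        subject_id = record$subject_id, event_time = te_raw, t = t, tau = tau,
        target_bg = bg_at(t + 10 + tau), tod_avg = mu_k[k], tod_idx = k,
        wall_min = wall, planned_carbs = events$planned_carbs[e],
        label = events$label[e])
      hist_l[[length(hist_l) + 1]] <- H
      win_l[[length(win_l) + 1]] <- W
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(subject_id = character(0), event_time = numeric(0), t = numeric(0),
               tau = numeric(0), target_bg = numeric(0), tod_avg = numeric(0),
               tod_idx = integer(0), wall_min = numeric(0),
               planned_carbs = numeric(0), label = numeric(0))
  structure(list(scenario = scenario, class = example_class, meta = meta,
                 history = hist_l, window = win_l, history_steps = history_steps),
            class = "rec_examples")
}

#' @export
print.rec_examples <- function(x, ...) {
  cat(sprintf("rec_examples: %d %s examples, scenario %s, %d events\n",
              nrow(x$meta), x$class, x$scenario,
              length(unique(x$meta$event_time))))
  invisible(x)
}

#' Subset examples by row index
#' @param x a `rec_examples`.
#' @param idx integer or logical index over examples.
#' @return a `rec_examples` with the selected rows.
#' @export
examples_subset <- function(x, idx) {
  if (is.logical(idx)) idx <- which(idx)
  x$meta <- x$meta[idx, , drop = FALSE]
  rownames(x$meta) <- NULL
  x$history <- x$history[idx]
  x$window <- x$window[idx]
  x
}

#' Concatenate example sets (same scenario/class)
#' @param ... `rec_examples` objects.
#' @return a combined `rec_examples`.
#' @export
examples_rbind <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, function(x) nrow(x$meta) > 0, TRUE)]
  if (!length(xs)) stop("no non-empty example sets")
  out <- xs[[1]]
  out$meta <- do.call(rbind, lapply(xs, `[[`, "meta"))
  rownames(out$meta) <- NULL
  out$history <- do.call(c, lapply(xs, `[[`, "history"))
  out$window <- do.call(c, lapply(xs, `[[`, "window"))
  out
}

#' Per-subject scenario eligibility report
#'
#' Counts qualifying events per split for a scenario and applies a minimum
#' event threshold, mirroring per-subject exclusions made when test data are
#' too sparse (e.g. requiring at least 50 carbohydrate events without a bolus
#' for the carbs-without-bolus scenario).
#'
#' @param records list of split `subject_record` lists as returned by
#'   [split_record()] (elements `train`, `validation`, `test`).
#' @param scenario one of [SCENARIOS].
#' @param min_events minimum total qualifying events (default 1; 50 mirrors
#'   the carbs-without-bolus rule).
#' @return data.frame with per-subject counts and an `eligible` flag.
#' @export
eligibility_report <- function(records, scenario, min_events = 1) {
  rows <- lapply(records, function(sp) {
    n <- vapply(sp[c("train", "validation", "test")],
                function(r) nrow(scenario_events(r, scenario)), 0L)
    data.frame(subject_id = sp$train$subject_id, train = n[1], validation = n[2],
               test = n[3])
  })
  out <- do.call(rbind, rows)
  out$eligible <- (out$train + out$validation + out$test) >= min_events &
    out$test > 0 & out$validation > 0
  rownames(out) <- NULL
  out
}
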