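#' Simulation configuration for synthetic subjects
#'
#' The simulator emulates the structure of pump/CGM study data - not human
#' physiology - with a linear-response glucose model that admits a closed-form
#' recommendation oracle. Glucose is an equilibrium-reverting noise process
#' plus superimposed event responses: a meal of `C` grams adds
#' `C * carb_potency * g_c(lag)` mg/dL and a bolus of `D` units subtracts
#' `D * ISF * g_i(lag)` mg/dL, where `g_c`/`g_i` are triangular response
#' kernels normalised to sum to 1 over their support (so a meal's total
#' excursion area is `C * carb_potency`). Basal insulin is assumed balanced
#' into the equilibrium and has no further glucose effect.
#'
#' Logging noise reproduces the phenomena the pre-processing has to fix:
#' smartphone meal timestamps jittered relative to the pump bolus (uniform
#' -30..+20 min), missing smartphone logs, noisy smartphone carb estimates,
#' bolus-wizard overrides (about a fifth of doses changed by a factor
#' 0.8-1.2), occasional dual boluses, and CGM gaps.
#'
#' @param seed RNG seed; same seed, identical record.
#' @param days record length (default 55, about 8 weeks).
#' @param carb_ratio grams of carbohydrate per unit of insulin, one value per
#'   time-of-day window (length 5).
#' @param isf insulin sensitivity, mg/dL per unit, per time-of-day window.
#' @param bg_target bolus-wizard target, mg/dL.
#' @param bg_equilibrium resting glucose, mg/dL.
#' @param revert_rate mean-reversion per 5-min step of the noise process.
#' @param carb_potency mg/dL rise per gram (total over the kernel support).
#' @param carb_peak,carb_support,insulin_peak,insulin_support kernel shape,
#'   minutes.
#' @param cgm_sd stationary CGM noise, mg/dL (0 gives a noise-free record).
#' @param gap_prob per-day probability of a CGM gap.
#' @param gap_range gap length range, minutes.
#' @param snack_prob per-day probability of an un-bolused bedtime snack.
#' @param hypo_threshold,hypo_carbs hypo-correction rule: glucose below the
#'   threshold triggers a `hypo_carbs`-gram un-bolused snack.
#' @param log_jitter smartphone timestamp jitter range, minutes.
#' @param log_missing probability a meal is never logged on the smartphone.
#' @param carb_est_sd relative sd of the smartphone carb estimate.
#' @param override_prob probability the bolus-wizard recommendation is
#'   overridden.
#' @param override_range multiplicative override range.
#' @param dual_prob probability a bolus is delivered as a dual bolus.
#' @param basal_day,basal_night basal rates, u/h.
#' @param correction_prob per-day probability of a stand-alone hyperglycemia
#'   correction bolus (no meal, no bolus-wizard carb entry).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, days = 55,
                       carb_ratio = c(12, 10, 9, 8, 10),
                       isf = c(45, 40, 35, 35, 40),
                       bg_target = 110, bg_equilibrium = 120, revert_rate = 0.1,
                       carb_potency = 3.5, carb_peak = 45, carb_support = 180,
                       insulin_peak = 75, insulin_support = 300,
                       cgm_sd = 5, gap_prob = 0.3, gap_range = c(15, 120),
                       snack_prob = 0.35, hypo_threshold = 70, hypo_carbs = 16,
                       log_jitter = c(-30, 20), log_missing = 0.15,
                       carb_est_sd = 0.1,
                       override_prob = 0.2, override_range = c(0.8, 1.2),
                       dual_prob = 0.05, basal_day = 1.1, basal_night = 0.8,
                       correction_prob = 0.5) {
  stopifnot(length(carb_ratio) == 5, length(isf) == 5,
            all(c(gap_prob, snack_prob, log_missing, override_prob, dual_prob) >= 0),
            all(c(gap_prob, snack_prob, log_missing, override_prob, dual_prob) <= 1))
  structure(as.list(environment()), class = "sim_config")
}

# triangular response kernel over 5-min lags, normalised to sum to 1
tri_kernel <- function(peak, support) {
  lags <- seq(5, support, by = 5)
  w <- ifelse(lags <= peak, lags / peak, (support - lags) / (support - peak))
  w <- pmax(w, 0)
  w / sum(w)
}

#' Deterministic glucose trace of the linear response model
#'
#' Evaluates the noise-free simulated glucose at the given times: the
#' equilibrium level plus the triangular-kernel responses of the supplied
#' events. This is the forward model the recommendation oracle inverts; it is
#' exported so oracle outputs can be verified by direct simulation.
#'
#' @param times evaluation times, minutes (vectorised).
#' @param meals data.frame with `time` and `carbs` columns.
#' @param boluses data.frame with `time`, `dose` and `isf` columns (`isf` is
#'   the sensitivity in effect at delivery time).
#' @param config a [sim_config()].
#' @return numeric vector of glucose values, mg/dL.
#' @export
noise_free_bg <- function(times, meals, boluses, config) {
  kc <- tri_kernel(config$carb_peak, config$carb_support)
  ki <- tri_kernel(config$insulin_peak, config$insulin_support)
  bg <- rep(config$bg_equilibrium, length(times))
  add_effect <- function(bg, t0, scale, kern) {
    lagidx <- (times - t0) / 5
    hit <- lagidx >= 1 & lagidx <= length(kern)
    bg[hit] <- bg[hit] + scale * kern[lagidx[hit]]
    bg
  }
  for (i in seq_len(nrow(meals)))
    bg <- add_effect(bg, meals$time[i], meals$carbs[i] * config$carb_potency, kc)
  for (i in seq_len(nrow(boluses)))
    bg <- add_effect(bg, boluses$time[i], -boluses$dose[i] * boluses$isf[i], ki)
  bg
}

#' Simulate one synthetic subject
#'
#' Generates a raw (pre-anchoring) record: pump streams are ground-truth timed
#' (boluses 10 min before their meals, with the bolus-wizard carb entry and
#' basal segments), the CGM trace has noise and gaps, and the smartphone meal
#' log is jittered, noisy and incomplete per the configuration. Hypo
#' corrections are added iteratively wherever the simulated glucose dips below
#' the threshold. Ground truth (true meals, boluses, recommended vs delivered
#' doses) is attached as `attr(record, "truth")`.
#'
#' @param config a [sim_config()].
#' @return a `subject_record` starting at midnight.
#' @export
simulate_subject <- function(config) {
  if (config$days < 21)
    warning("records of 21 days or fewer cannot be split 10/10 for validation/test")
  set.seed(config$seed)
  n_steps <- config$days * 288
  times <- seq(0, (n_steps - 1) * 5, by = 5)

  rnorm_pos <- function(n, mean, sd, lo) pmax(round(stats::rnorm(n, mean, sd)), lo)
  meal_plan <- list()
  for (d in seq_len(config$days) - 1) {
    day0 <- d * 1440
    sched <- rbind(
      data.frame(time = 450 + stats::runif(1, -30, 30), carbs = rnorm_pos(1, 50, 10, 15), bolused = TRUE),
      data.frame(time = 750 + stats::runif(1, -40, 40), carbs = rnorm_pos(1, 60, 12, 15), bolused = TRUE),
      data.frame(time = 1110 + stats::runif(1, -40, 40), carbs = rnorm_pos(1, 70, 14, 15), bolused = TRUE))
    if (stats::runif(1) < config$snack_prob)
      sched <- rbind(sched, data.frame(time = 1290 + stats::runif(1, -30, 30),
                                       carbs = rnorm_pos(1, 20, 5, 8), bolused = FALSE))
    sched$time <- grid_snap(day0 + sched$time)
    meal_plan[[d + 1]] <- sched
  }
  meals_true <- do.call(rbind, meal_plan)
  meals_true <- meals_true[order(meals_true$time), ]
  meals_true <- meals_true[meals_true$time >= 360 & meals_true$time <= max(times) - 10, ]

  # equilibrium-reverting noise, stationary sd = cgm_sd
  lam <- config$revert_rate
  innov_sd <- config$cgm_sd * sqrt(1 - (1 - lam)^2)
  noise <- numeric(n_steps)
  eps <- stats::rnorm(n_steps, 0, innov_sd)
  for (k in 2:n_steps) noise[k] <- (1 - lam) * noise[k - 1] + eps[k]

  # boluses via the simulated bolus wizard (dose for carbs + correction)
  bol <- list()
  bg_now <- function(meals, boluses, t) {
    noise_free_bg(t, meals, boluses, config) + noise[t / 5 + 1]
  }
  empty_bol <- data.frame(time = numeric(0), dose = numeric(0), isf = numeric(0),
                          recommended = numeric(0), kind = character(0),
                          bw_carb_input = numeric(0))
  boluses <- empty_bol
  for (i in seq_len(nrow(meals_true))) {
    if (!meals_true$bolused[i]) next
    tb <- meals_true$time[i] - 10
    if (tb < 0) next
    k <- tod_interval(tb %% 1440)
    bg_b <- bg_now(meals_true[seq_len(i - 1), , drop = FALSE], boluses, tb)
    rec_dose <- meals_true$carbs[i] / config$carb_ratio[k] +
      max(0, bg_b - config$bg_target) / config$isf[k]
    dose <- rec_dose
    if (stats::runif(1) < config$override_prob)
      dose <- dose * stats::runif(1, config$override_range[1], config$override_range[2])
    dose <- max(round(dose, 1), 0.1)
    kind <- if (stats::runif(1) < config$dual_prob) "dual" else "normal"
    boluses <- rbind(boluses, data.frame(time = tb, dose = dose, isf = config$isf[k],
                                         recommended = rec_dose, kind = kind,
                                         bw_carb_input = meals_true$carbs[i]))
  }

  # stand-alone hyperglycemia-correction boluses (no meal, no BW carb entry);
  # these populate the all-boluses scenario with inertial examples
  for (d in seq_len(config$days) - 1) {
    if (stats::runif(1) >= config$correction_prob) next
    tc <- grid_snap(d * 1440 + stats::runif(1, 900, 1260))
    if (any(abs(meals_true$time - tc) < 75) || any(abs(boluses$time - tc) < 75)) next
    k <- tod_interval(tc %% 1440)
    bg_c <- bg_now(meals_true, boluses, tc)
    dose <- round(max(bg_c - config$bg_target, 10) / config$isf[k], 1)
    dose <- max(dose, 0.3)
    boluses <- rbind(boluses, data.frame(time = tc, dose = dose, isf = config$isf[k],
                                         recommended = dose, kind = "normal",
                                         bw_carb_input = NA_real_))
  }
  boluses <- boluses[order(boluses$time), ]

  # hypo corrections: recompute until no new dips below threshold
  meals_all <- meals_true
  for (pass in 1:5) {
    bg <- noise_free_bg(times, meals_all, boluses, config) + noise
    low <- which(bg < config$hypo_threshold)
    low <- low[times[low] > 360]
    if (!length(low)) break
    newt <- c()
    last <- -Inf
    for (ix in low) {
      tt <- times[ix]
      near_prior <- any(abs(meals_all$time[meals_all$carbs == config$hypo_carbs] - tt) < 60)
      if (tt - last >= 60 && !near_prior) {
        newt <- c(newt, tt + 5)
        last <- tt
      }
    }
    if (!length(newt)) break
    meals_all <- rbind(meals_all, data.frame(time = newt, carbs = config$hypo_carbs,
                                             bolused = FALSE))
    meals_all <- meals_all[order(meals_all$time), ]
  }
  bg <- noise_free_bg(times, meals_all, boluses, config) + noise

  # CGM gaps
  keep <- rep(TRUE, n_steps)
  for (d in seq_len(config$days) - 1) {
    if (stats::runif(1) < config$gap_prob) {
      len <- 5 * round(stats::runif(1, config$gap_range[1], config$gap_range[2]) / 5)
      start <- d * 1440 + 5 * floor(stats::runif(1, 0, (1440 - len) / 5))
      keep[times >= start & times < start + len] <- FALSE
    }
  }
  keep[1] <- TRUE; keep[n_steps] <- TRUE   # anchor the record span

  # smartphone meal log: jittered, noisy, incomplete
  logged <- stats::runif(nrow(meals_all)) >= config$log_missing
  log_meals <- meals_all[logged, , drop = FALSE]
  if (nrow(log_meals)) {
    jit <- stats::runif(nrow(log_meals), config$log_jitter[1], config$log_jitter[2])
    est <- pmax(round(log_meals$carbs * stats::rnorm(nrow(log_meals), 1, config$carb_est_sd)), 1)
    log_meals <- data.frame(time = round(log_meals$time + jit), carbs = est,
                            source = "smartphone", shifted = FALSE, added = FALSE)
    log_meals <- log_meals[log_meals$time >= 0, , drop = FALSE]
  }

  # basal: day/night pattern
  seg <- list()
  for (d in seq_len(config$days) - 1) {
    day0 <- d * 1440
    seg[[length(seg) + 1]] <- data.frame(start = day0, end = day0 + 360, rate = config$basal_night)
    seg[[length(seg) + 1]] <- data.frame(start = day0 + 360, end = day0 + 1320, rate = config$basal_day)
    seg[[length(seg) + 1]] <- data.frame(start = day0 + 1320, end = day0 + 1440, rate = config$basal_night)
  }
  basal <- do.call(rbind, seg)
  basal$end <- pmin(basal$end, max(times) + 5)
  basal <- basal[basal$start < basal$end, ]

  rec <- subject_record(
    subject_id = sprintf("sim%03d", config$seed %% 1000),
    glucose = data.frame(time = times[keep], value = bg[keep], interpolated = FALSE),
    boluses = boluses[, c("time", "dose", "kind", "bw_carb_input")],
    meals = log_meals,
    basal = basal,
    start_wall = as.POSIXct("2021-07-01 00:00:00", tz = "UTC"))
  attr(rec, "truth") <- list(meals = meals_all, boluses = boluses, noise = noise,
                             config = config)
  rec
}

#' Closed-form recommendation oracle on the noise-free simulator
#'
#' Returns the exact event magnitude at `t + 10` that makes the noise-free
#' simulated glucose hit `target_bg` at `t + 10 + tau`, by inverting the
#' linear response model: for a bolus, `dose = (no-action BG - target) /
#' (ISF * g_i(tau))`; for carbs, `carbs = (target - no-action BG) /
#' (potency * g_c(tau))`, where `g(tau)` is the response-kernel ordinate at
#' lag `tau`. Infeasible targets (requiring a negative dose or carbs, or a
#' lag outside the kernel support) raise an error.
#'
#' @param truth ground-truth event list from `attr(record, "truth")`, or any
#'   list with `meals` (time, carbs) and `boluses` (time, dose, isf).
#' @param scenario a carb scenario (recommend carbs) or bolus scenario
#'   (recommend a dose); see [SCENARIOS].
#' @param t present time, minutes.
#' @param tau horizon, minutes.
#' @param target_bg desired glucose at `t + 10 + tau`, mg/dL.
#' @param config the [sim_config()] used to generate the record.
#' @return the recommended magnitude (g or u).
#' @export
oracle_recommendation <- function(truth, scenario, t, tau, target_bg, config) {
  scenario <- match.arg(scenario, SCENARIOS)
  noaction <- noise_free_bg(t + 10 + tau, truth$meals, truth$boluses, config)
  if (scenario %in% c("carbs_pm_b", "carbs_m_b")) {
    kern <- tri_kernel(config$carb_peak, config$carb_support)
    if (tau / 5 > length(kern) || kern[tau / 5] <= 0)
      stop("carb response is zero at lag ", tau, " min; target unreachable")
    val <- (target_bg - noaction) / (config$carb_potency * kern[tau / 5])
    if (val < 0) stop("target below the no-action glucose: would need negative carbs")
  } else {
    kern <- tri_kernel(config$insulin_peak, config$insulin_support)
    k <- tod_interval((t + 10) %% 1440)
    if (tau / 5 > length(kern) || kern[tau / 5] <= 0)
      stop("insulin response is zero at lag ", tau, " min; target unreachable")
    val <- (noaction - target_bg) / (config$isf[k] * kern[tau / 5])
    if (val < 0) stop("target above the no-action glucose: would need a negative dose")
  }
  val
}

#' Generate a multi-subject synthetic benchmark
#'
#' Simulates `n_subjects` records with per-subject parameter variation
#' (carb ratios, insulin sensitivities, equilibrium glucose drawn around the
#' base configuration), optionally writes them in both the XML and CSV
#' formats plus a JSON manifest of per-subject event counts and ground-truth
#' configurations.
#'
#' @param n_subjects number of subjects (default 12).
#' @param seed master seed (default 42); subject `i` uses `seed + 1000 * i`.
#' @param days record length per subject.
#' @param dir output directory, or NULL to skip writing.
#' @param force overwrite an existing output directory.
#' @param cgm_sd CGM noise level passed through to [sim_config()].
#' @return list with `records` (each carrying its truth attribute),
#'   `configs`, and `manifest` (data.frame of per-subject counts).
#' @export
make_benchmark <- function(n_subjects = 12, seed = 42, days = 55, dir = NULL,
                           force = FALSE, cgm_sd = 5) {
  set.seed(seed)
  subj_seed <- seed + 1000 * seq_len(n_subjects)
  vary <- function(x, f) x * stats::runif(length(x), 1 - f, 1 + f)
  configs <- lapply(seq_len(n_subjects), function(i) {
    sim_config(seed = subj_seed[i], days = days,
               carb_ratio = round(vary(c(12, 10, 9, 8, 10), 0.2), 1),
               isf = round(vary(c(45, 40, 35, 35, 40), 0.2)),
               bg_equilibrium = round(stats::runif(1, 110, 135)),
               cgm_sd = cgm_sd)
  })
  records <- lapply(configs, simulate_subject)
  manifest <- do.call(rbind, lapply(records, function(r) {
    tr <- attr(r, "truth")
    data.frame(subject_id = r$subject_id,
               n_meals_true = nrow(tr$meals),
               n_meals_logged = nrow(r$meals),
               n_meals_unbolused = sum(!tr$meals$bolused),
               n_boluses = nrow(r$boluses),
               n_dual = sum(r$boluses$kind == "dual"),
               n_overridden = sum(abs(tr$boluses$dose - tr$boluses$recommended) > 0.051),
               mean_carbs = round(mean(tr$meals$carbs), 1),
               mean_dose = round(mean(r$boluses$dose), 2),
               days = days)
  }))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !force)
      stop("output directory ", dir, " exists; use force = TRUE")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (r in records) {
      write_subject(r, file.path(dir, paste0(r$subject_id, ".xml")), "ohio_xml")
      write_subject(r, file.path(dir, r$subject_id), "csv")
    }
    jsonlite::write_json(list(seed = seed, n_subjects = n_subjects, days = days,
                              manifest = manifest),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(records = records, configs = configs, manifest = manifest)
}
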