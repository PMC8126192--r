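#' Anchor self-reported meals to their bolus timestamps
#'
#' Self-reported meal timestamps from a smartphone interface are unreliable
#' relative to the pump clock: many meals are logged before the bolus that
#' covered them. Since subjects were instructed to bolus 10 minutes before
#' eating, this step re-anchors meals to the pump record. For every bolus with
#' a positive bolus-wizard carbohydrate input, processed in chronological
#' order, the closest not-yet-consumed smartphone meal within `match_window`
#' minutes (before or after) is moved to exactly `bolus time + 10` and its
#' carbs replaced by the bolus-wizard grams (flag `shifted`). Ties in distance
#' are broken toward the meal whose logged carbs are closest to the
#' bolus-wizard grams, then toward the earlier meal. When no meal is found in
#' the window, the subject is assumed to have forgotten to log it, and a meal
#' is created at `bolus time + 10` with the bolus-wizard grams (flag `added`,
#' source `"bolus_wizard"`). Meals not claimed by any bolus are untouched.
#' Correction boluses (zero or absent carb input) anchor nothing.
#'
#' The operation is idempotent: an already-anchored meal sits exactly 10
#' minutes after its bolus with identical carbs, so it is re-selected and
#' re-anchored in place on a second pass.
#'
#' @param record a `subject_record`.
#' @param match_window maximum meal--bolus distance in minutes (default 60).
#' @return the record with anchored meals and `anchored = TRUE`. Original
#'   timestamp/carbs of shifted meals are retained in `orig_time`/`orig_carbs`
#'   as provenance.
#' @export
anchor_meals <- function(record, match_window = 60) {
  meals <- record$meals
  if (is.null(meals$orig_time)) meals$orig_time <- meals$time
  if (is.null(meals$orig_carbs)) meals$orig_carbs <- meals$carbs
  bol <- record$boluses
  if (nrow(bol) && any(!is.na(bol$bw_carb_input) & bol$bw_carb_input < 0))
    stop("negative bw_carb_input")
  consumed <- rep(FALSE, nrow(meals))
  for (i in seq_len(nrow(bol))) {
    bw <- bol$bw_carb_input[i]
    if (is.na(bw) || bw <= 0) next
    bt <- bol$time[i]
    cand <- which(!consumed & abs(meals$time - bt) <= match_window)
    if (length(cand)) {
      d <- abs(meals$time[cand] - bt)
      cand <- cand[d == min(d)]
      if (length(cand) > 1) {   # carb closeness, then earlier meal
        cd <- abs(meals$carbs[cand] - bw)
        cand <- cand[cd == min(cd)]
        cand <- cand[order(meals$time[cand])][1]
      }
      already <- meals$time[cand] == bt + 10 && meals$carbs[cand] == bw
      if (!already) {   # no-op on an already-anchored meal keeps idempotence
        meals$time[cand] <- bt + 10
        meals$carbs[cand] <- bw
        meals$shifted[cand] <- TRUE
      }
      consumed[cand] <- TRUE
    } else {
      meals <- rbind(meals, data.frame(time = bt + 10, carbs = bw,
                                       source = "bolus_wizard", shifted = FALSE,
                                       added = TRUE, orig_time = NA_real_,
                                       orig_carbs = NA_real_))
      consumed <- c(consumed, TRUE)
    }
  }
  record$meals <- meals[order(meals$time), , drop = FALSE]
  rownames(record$meals) <- NULL
  record$anchored <- TRUE
  record
}

#' Fill CGM gaps by linear interpolation on the 5-minute grid
#'
#' Every interior grid step between the first and last measured glucose sample
#' gets a value, linear in time between the flanking measurements and flagged
#' `interpolated = TRUE`. Measured samples are unchanged; nothing is
#' extrapolated beyond the measured range.
#'
#' @param record a `subject_record` with at least two measured samples.
#' @return the record with a gap-free glucose stream and `interpolated = TRUE`
#'   (record-level flag meaning the step has been applied).
#' @export
interpolate_glucose <- function(record) {
  g <- record$glucose
  meas <- g[!g$interpolated, , drop = FALSE]
  if (nrow(meas) < 2) stop("need at least 2 measured glucose samples")
  grid <- seq(min(meas$time), max(meas$time), by = 5)
  filled <- data.frame(time = grid,
                       value = stats::approx(meas$time, meas$value, xout = grid)$y,
                       interpolated = !(grid %in% meas$time))
  # keep exact measured values (approx reproduces them, but avoid FP drift)
  filled$value[!filled$interpolated] <- meas$value[match(grid[!filled$interpolated], meas$time)]
  record$glucose <- filled
  record$interpolated <- TRUE
  record
}

#' Example admissibility under the interpolation filters
#'
#' An example anchored at present time `t` with horizon `tau` is inadmissible
#' when any of the following holds: the glucose target at `t + 10 + tau` is
#' interpolated (or beyond the data), the glucose at `t` is interpolated or
#' missing, more than 2 samples in the hour `(t-60, t]` are interpolated, or
#' more than 12 samples in the six hours `(t-360, t]` are interpolated.
#'
#' @param t present grid time, minutes.
#' @param tau prediction horizon, minutes.
#' @param record an interpolated `subject_record`.
#' @param quiet suppress the log message when the horizon falls outside data.
#' @return logical.
#' @export
is_admissible <- function(t, tau, record, quiet = TRUE) {
  g <- record$glucose
  target_t <- t + 10 + tau
  it <- match(target_t, g$time)
  if (is.na(it)) {
    if (!quiet) message("horizon outside data at t=", t, " tau=", tau)
    return(FALSE)
  }
  if (g$interpolated[it]) return(FALSE)
  i0 <- match(t, g$time)
  if (is.na(i0) || g$interpolated[i0]) return(FALSE)
  in_hour <- g$time > t - 60 & g$time <= t
  if (sum(g$interpolated[in_hour]) > 2) return(FALSE)
  in_six <- g$time > t - 360 & g$time <= t
  if (sum(g$interpolated[in_six]) > 12) return(FALSE)
  TRUE
}

#' Min--max scaler fitted on training data
#'
#' Maps each channel's training minimum to 0 and maximum to 1; values outside
#' the training range map linearly outside `[0, 1]` (no clipping), so
#' out-of-range test values remain informative. Channels are `bg`, `carbs`,
#' `bolus`, `basal` (taken from a gridded training series) and `label` (the
#' recommendation target magnitudes).
#'
#' @param train a `gridded_series` from the training split.
#' @param labels numeric vector of training label values (g or u).
#' @return an object of class `rec_scaler`: per-channel `min`/`max`.
#' @export
fit_scaler <- function(train, labels) {
  rng <- function(x, channel) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("no data to fit scaler channel '", channel, "'")
    r <- range(x)
    if (r[1] == r[2]) stop("constant channel '", channel, "': max equals min")
    r
  }
  ranges <- list(bg = rng(train$bg, "bg"), carbs = rng(train$carbs, "carbs"),
                 bolus = rng(train$bolus, "bolus"), basal = rng(train$basal, "basal"),
                 label = rng(labels, "label"))
  structure(list(min = vapply(ranges, `[`, 0, 1),
                 max = vapply(ranges, `[`, 0, 2)), class = "rec_scaler")
}

#' Scale a value into training-range [0,1] units
#' @param x numeric.
#' @param scaler a `rec_scaler`.
#' @param channel one of `"bg" "carbs" "bolus" "basal" "label"`.
#' @return scaled numeric.
#' @export
scale_channel <- function(x, scaler, channel) {
  (x - scaler$min[[channel]]) / (scaler$max[[channel]] - scaler$min[[channel]])
}

#' Invert [scale_channel()]
#' @inheritParams scale_channel
#' @export
unscale_channel <- function(x, scaler, channel) {
  x * (scaler$max[[channel]] - scaler$min[[channel]]) + scaler$min[[channel]]
}
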