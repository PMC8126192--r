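#' Bin a subject record onto the 5-minute grid
#'
#' Produces a multichannel series with one row per 5-minute step from minute 0
#' to the end of the record: glucose (`bg`, NA where no sample exists), summed
#' meal carbohydrates (`carbs`, g), summed bolus doses (`bolus`, u), basal
#' insulin actually delivered during the bin (`basal`, u = rate x 5/60), and
#' the glucose interpolation flag. Event times are assigned to the nearest grid
#' point, ties rounding down; multiple events falling in one bin are summed, so
#' channel totals are conserved exactly.
#'
#' @param record a `subject_record`.
#' @return a data.frame of class `gridded_series` with columns
#'   `time, bg, carbs, bolus, basal, interpolated`.
#' @export
to_grid <- function(record) {
  validate_record(record)
  span <- record_span(record)
  if (span[1] < 0) stop("event before record start (negative time)")
  end <- 5 * ceiling(span[2] / 5)
  times <- seq(0, end, by = 5)
  n <- length(times)
  bg <- rep(NA_real_, n); interp <- rep(FALSE, n)
  gi <- grid_snap(record$glucose$time) / 5 + 1
  bg[gi] <- record$glucose$value
  interp[gi] <- record$glucose$interpolated
  carbs <- bin_sum(record$meals$time, record$meals$carbs, n)
  bolus <- bin_sum(record$boluses$time, record$boluses$dose, n)
  basal <- rep(0, n)
  if (nrow(record$basal)) {
    for (s in seq_len(nrow(record$basal))) {
      seg <- record$basal[s, ]
      # overlap of [time, time+5) with the segment, in hours, times rate
      ov <- pmax(0, pmin(times + 5, seg$end) - pmax(times, seg$start))
      basal <- basal + seg$rate * ov / 60
    }
  }
  structure(data.frame(time = times, bg = bg, carbs = carbs, bolus = bolus,
                       basal = basal, interpolated = interp),
            class = c("gridded_series", "data.frame"))
}

bin_sum <- function(time, amount, n) {
  out <- rep(0, n)
  if (length(time)) {
    idx <- grid_snap(time) / 5 + 1
    agg <- tapply(amount, idx, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Chronological train/validation/test split
#'
#' Splits one record into three by calendar time: the last 10 days form the
#' test portion, the 10 days before that the validation portion, and the
#' remainder the training portion. Events are partitioned by their timestamps;
#' basal segments are clipped at the boundaries. Record times stay on the
#' original clock so splits can be related back to the full record.
#'
#' @param record a `subject_record` spanning more than 20 days.
#' @param test_days,val_days portion lengths in days (defaults 10 and 10).
#' @return a list with elements `train`, `validation`, `test`
#'   (each a `subject_record`) and `boundaries = c(train_end, val_end)`.
#' @export
split_record <- function(record, test_days = 10, val_days = 10) {
  span <- record_span(record)
  span_days <- (span[2] - span[1]) / 1440
  if (span_days <= test_days + val_days)
    stop(sprintf(paste("record spans %.1f days, need more than %d;",
                       "pass explicit boundaries via subset_record for short records"),
                 span_days, test_days + val_days))
  val_start <- span[2] - (test_days + val_days) * 1440
  test_start <- span[2] - test_days * 1440
  record$split <- c(val_start, test_start)
  list(train = subset_record(record, span[1], val_start),
       validation = subset_record(record, val_start, test_start),
       test = subset_record(record, test_start, span[2] + 5),
       boundaries = c(train_end = val_start, val_end = test_start))
}

#' Restrict a record to a half-open time window [from, to)
#'
#' @param record a `subject_record`.
#' @param from,to window boundaries in minutes.
#' @return a `subject_record` containing only events with `from <= time < to`;
#'   basal segments are clipped to the window.
#' @export
subset_record <- function(record, from, to) {
  b <- record$basal
  if (nrow(b)) {
    b <- b[b$end > from & b$start < to, , drop = FALSE]
    if (nrow(b)) {
      b$start <- pmax(b$start, from)
      b$end <- pmin(b$end, to)
    }
  }
  out <- record
  out$glucose <- record$glucose[record$glucose$time >= from & record$glucose$time < to, , drop = FALSE]
  out$boluses <- record$boluses[record$boluses$time >= from & record$boluses$time < to, , drop = FALSE]
  out$meals <- record$meals[record$meals$time >= from & record$meals$time < to, , drop = FALSE]
  out$basal <- b
  out$split <- NULL
  rownames(out$glucose) <- NULL; rownames(out$boluses) <- NULL
  rownames(out$meals) <- NULL; rownames(out$basal) <- NULL
  out
}
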