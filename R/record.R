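#' Subject records of CGM, bolus, basal, and meal event streams
#'
#' A `subject_record` holds one person's event streams in the layout used by
#' pump/CGM study exports: a CGM glucose trace sampled every 5 minutes, discrete
#' insulin boluses (with the carbohydrate grams entered into the pump's bolus
#' wizard, when available), piecewise-constant basal rates, and self-reported
#' meals. All times are integer minutes since the subject's record start; the
#' wall-clock start is retained separately so time-of-day features can be
#' derived.
#'
#' @param subject_id character scalar identifier.
#' @param glucose data.frame with columns `time` (min), `value` (mg/dL) and
#'   optionally `interpolated` (logical; defaults to FALSE).
#' @param boluses data.frame with columns `time`, `dose` (units), `kind`
#'   (`"normal"` or `"dual"`) and `bw_carb_input` (grams entered into the bolus
#'   wizard; `NA` when the wizard was not used).
#' @param meals data.frame with columns `time`, `carbs` (g), `source`
#'   (`"smartphone"`, `"bolus_wizard"` or `"synthetic"`), `shifted`, `added`.
#' @param basal data.frame with columns `start`, `end` (min) and `rate` (u/h).
#' @param start_wall POSIXct wall-clock time of minute 0 (used for time-of-day).
#' @param split optional numeric `c(train_end, val_end)` boundaries in minutes.
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(subject_id, glucose, boluses = NULL, meals = NULL,
                           basal = NULL, start_wall = as.POSIXct("2021-07-01 00:00:00", tz = "UTC"),
                           split = NULL) {
  glucose <- as.data.frame(glucose)
  if (is.null(glucose$interpolated)) glucose$interpolated <- FALSE
  if (is.null(boluses) || nrow(as.data.frame(boluses)) == 0) {
    boluses <- data.frame(time = numeric(0), dose = numeric(0),
                          kind = character(0), bw_carb_input = numeric(0))
  } else {
    boluses <- as.data.frame(boluses)
    if (is.null(boluses$kind)) boluses$kind <- "normal"
    if (is.null(boluses$bw_carb_input)) boluses$bw_carb_input <- NA_real_
  }
  if (is.null(meals) || nrow(as.data.frame(meals)) == 0) {
    meals <- data.frame(time = numeric(0), carbs = numeric(0), source = character(0),
                        shifted = logical(0), added = logical(0))
  } else {
    meals <- as.data.frame(meals)
    if (is.null(meals$source)) meals$source <- "smartphone"
    if (is.null(meals$shifted)) meals$shifted <- FALSE
    if (is.null(meals$added)) meals$added <- FALSE
  }
  if (is.null(basal) || nrow(as.data.frame(basal)) == 0) {
    basal <- data.frame(start = numeric(0), end = numeric(0), rate = numeric(0))
  } else {
    basal <- as.data.frame(basal)
  }
  rec <- structure(list(
    subject_id = as.character(subject_id),
    glucose = glucose[order(glucose$time), , drop = FALSE],
    boluses = boluses[order(boluses$time), , drop = FALSE],
    meals = meals[order(meals$time), , drop = FALSE],
    basal = basal[order(basal$start), , drop = FALSE],
    start_wall = start_wall,
    split = split,
    anchored = FALSE,
    interpolated = FALSE
  ), class = "subject_record")
  rownames(rec$glucose) <- NULL; rownames(rec$boluses) <- NULL
  rownames(rec$meals) <- NULL; rownames(rec$basal) <- NULL
  validate_record(rec)
  rec
}

#' Validate a subject record's invariants
#'
#' Checks stream ordering, positivity of glucose and carbs, non-negative doses,
#' and basal segment consistency. Called by the constructor; exported so readers
#' and simulators can re-check after transformation.
#'
#' @param record a `subject_record`.
#' @return the record, invisibly; stops on violation.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  g <- record$glucose
  if (nrow(g) == 0) stop("empty glucose stream in subject ", record$subject_id)
  if (any(g$value <= 0)) stop("glucose values must be positive")
  if (is.unsorted(g$time)) stop("glucose stream not time-sorted")
  if (nrow(record$boluses) && any(record$boluses$dose < 0)) stop("bolus dose must be >= 0")
  if (nrow(record$meals) && any(record$meals$carbs <= 0)) stop("meal carbs must be > 0")
  if (nrow(record$meals)) {
    bad <- record$meals$added & record$meals$source != "bolus_wizard"
    if (any(bad)) stop("added meals must have source 'bolus_wizard'")
  }
  b <- record$basal
  if (nrow(b)) {
    if (any(b$start >= b$end)) stop("basal segments need start < end")
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)] - 1e-9))
      stop("basal segments overlap")
  }
  if (!is.null(record$split)) {
    sp <- record$split
    if (length(sp) != 2 || sp[1] >= sp[2]) stop("split must be c(train_end, val_end) with train_end < val_end")
  }
  invisible(record)
}

#' @export
print.subject_record <- function(x, ...) {
  span <- record_span(x)
  cat(sprintf("subject_record '%s': %.1f days\n", x$subject_id, (span[2] - span[1]) / 1440))
  cat(sprintf("  glucose: %d samples (%d interpolated)\n",
              nrow(x$glucose), sum(x$glucose$interpolated)))
  cat(sprintf("  boluses: %d (%d dual)  meals: %d (%d shifted, %d added)  basal segments: %d\n",
              nrow(x$boluses), sum(x$boluses$kind == "dual"),
              nrow(x$meals), sum(x$meals$shifted), sum(x$meals$added), nrow(x$basal)))
  cat(sprintf("  anchored: %s  interpolated: %s\n", x$anchored, x$interpolated))
  if (!is.null(x$split))
    cat(sprintf("  split: train < %d min <= validation < %d min <= test\n",
                x$split[1], x$split[2]))
  invisible(x)
}

# span of the record in minutes over all streams
record_span <- function(record) {
  lo <- min(record$glucose$time,
            if (nrow(record$boluses)) record$boluses$time else Inf,
            if (nrow(record$meals)) record$meals$time else Inf,
            if (nrow(record$basal)) record$basal$start else Inf)
  hi <- max(record$glucose$time,
            if (nrow(record$boluses)) record$boluses$time else -Inf,
            if (nrow(record$meals)) record$meals$time else -Inf,
            if (nrow(record$basal)) record$basal$end else -Inf)
  c(lo, hi)
}

# wall-clock minute-of-day for a record time t (vectorised)
wall_minute <- function(record, t) {
  lt <- as.POSIXlt(record$start_wall)
  t0 <- lt$hour * 60 + lt$min + lt$sec / 60
  (t0 + t) %% 1440
}

# round to the nearest 5-minute grid point, ties rounding down
grid_snap <- function(t) 5 * ceiling(t / 5 - 0.5)
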