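#' Read a subject record from OhioT1DM-style XML or the package CSV dialect
#'
#' The XML layout follows the OhioT1DM distribution: a `<patient id=...>` root
#' with `<glucose_level>`, `<bolus>`, `<meal>` and `<basal>` children, each
#' holding `<event>` rows with `dd-mm-yyyy HH:MM:SS` timestamps. Any other
#' child element (heart rate, skin temperature, ...) is ignored with a warning.
#' Glucose timestamps are snapped to the 5-minute grid relative to the earliest
#' timestamp in the file; basal rate-change events become piecewise-constant
#' segments extending to the next change (the last to the record end).
#'
#' The CSV dialect stores one file per stream next to a JSON metadata file:
#' `<prefix>_glucose.csv` (time, value, interpolated), `<prefix>_bolus.csv`
#' (time, dose, kind, bw_carb_input), `<prefix>_meal.csv` (time, carbs, source,
#' shifted, added), `<prefix>_basal.csv` (start, end, rate) and
#' `<prefix>_meta.json` (subject_id, start_wall, split, flags). Times are
#' minutes from record start, so synthetic data needs no XML at all.
#'
#' @param path file path (XML) or file prefix (CSV dialect).
#' @param format `"ohio_xml"` or `"csv"`.
#' @return a `subject_record`.
#' @seealso [write_subject()]
#' @export
read_subject <- function(path, format = c("ohio_xml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") return(read_subject_csv(path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ", conditionMessage(e)))
  root <- doc
  if (xml2::xml_name(root) != "patient") stop("parse error: expected <patient> root, got <",
                                              xml2::xml_name(root), ">")
  subject_id <- xml2::xml_attr(root, "id")
  known <- c("glucose_level", "bolus", "meal", "basal")
  kids <- xml2::xml_children(root)
  other <- setdiff(unique(xml2::xml_name(kids)), known)
  if (length(other))
    warning("ignoring unknown record types: ", paste(other, collapse = ", "))

  parse_ts <- function(x) as.POSIXct(x, format = "%d-%m-%Y %H:%M:%S", tz = "UTC")
  ev <- function(stream, attr) {
    nodes <- xml2::xml_find_all(root, sprintf("./%s/event", stream))
    lapply(attr, function(a) xml2::xml_attr(nodes, a))
  }

  g <- ev("glucose_level", c("ts", "value"))
  if (length(g[[1]]) == 0) stop("empty glucose stream in ", path)
  g_ts <- parse_ts(g[[1]])
  if (anyNA(g_ts)) stop("parse error: bad timestamp in <glucose_level> of ", path)
  b <- ev("bolus", c("ts_begin", "type", "dose", "bwz_carb_input"))
  m <- ev("meal", c("ts", "carbs"))
  ba <- ev("basal", c("ts", "value"))
  b_ts <- parse_ts(b[[1]]); m_ts <- parse_ts(m[[1]]); ba_ts <- parse_ts(ba[[1]])

  start_wall <- min(c(g_ts, b_ts, m_ts, ba_ts), na.rm = TRUE)
  mins <- function(ts) as.numeric(difftime(ts, start_wall, units = "mins"))

  glucose <- data.frame(time = grid_snap(mins(g_ts)), value = as.numeric(g[[2]]),
                        interpolated = FALSE)
  boluses <- if (length(b_ts)) {
    data.frame(time = mins(b_ts), dose = as.numeric(b[[3]]),
               kind = ifelse(grepl("dual", b[[2]]), "dual", "normal"),
               bw_carb_input = suppressWarnings(as.numeric(b[[4]])))
  } else NULL
  meals <- if (length(m_ts)) {
    data.frame(time = mins(m_ts), carbs = as.numeric(m[[2]]),
               source = "smartphone", shifted = FALSE, added = FALSE)
  } else NULL
  basal <- if (length(ba_ts)) {
    bt <- mins(ba_ts); rate <- as.numeric(ba[[2]])
    end <- max(glucose$time) + 5
    data.frame(start = bt, end = c(bt[-1], end), rate = rate)
  } else NULL
  subject_record(subject_id, glucose, boluses, meals, basal, start_wall = start_wall)
}

#' Write a subject record to OhioT1DM-style XML or the CSV dialect
#'
#' @param record a `subject_record`.
#' @param path output file path (XML) or prefix (CSV).
#' @param format `"ohio_xml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_subject <- function(record, path, format = c("ohio_xml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") return(write_subject_csv(record, path))
  fmt_ts <- function(t) format(record$start_wall + t * 60, "%d-%m-%Y %H:%M:%S", tz = "UTC")
  doc <- xml2::xml_new_root("patient", id = record$subject_id)
  gl <- xml2::xml_add_child(doc, "glucose_level")
  for (i in seq_len(nrow(record$glucose)))
    xml2::xml_add_child(gl, "event", ts = fmt_ts(record$glucose$time[i]),
                        value = format(record$glucose$value[i], digits = 15))
  bo <- xml2::xml_add_child(doc, "bolus")
  for (i in seq_len(nrow(record$boluses))) {
    r <- record$boluses[i, ]
    xml2::xml_add_child(bo, "event", ts_begin = fmt_ts(r$time), ts_end = fmt_ts(r$time),
                        type = if (r$kind == "dual") "normal dual" else "normal",
                        dose = format(r$dose, digits = 15),
                        bwz_carb_input = if (is.na(r$bw_carb_input)) "" else format(r$bw_carb_input, digits = 15))
  }
  me <- xml2::xml_add_child(doc, "meal")
  for (i in seq_len(nrow(record$meals))) {
    r <- record$meals[i, ]
    xml2::xml_add_child(me, "event", ts = fmt_ts(r$time), type = "meal",
                        carbs = format(r$carbs, digits = 15))
  }
  ba <- xml2::xml_add_child(doc, "basal")
  for (i in seq_len(nrow(record$basal)))
    xml2::xml_add_child(ba, "event", ts = fmt_ts(record$basal$start[i]),
                        value = format(record$basal$rate[i], digits = 15))
  xml2::write_xml(doc, path)
  invisible(path)
}

read_subject_csv <- function(prefix) {
  f <- function(s) paste0(prefix, "_", s, ".csv")
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(f("glucose"))) stop("missing ", f("glucose"))
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  rd <- function(s) if (file.exists(f(s))) utils::read.csv(f(s)) else NULL
  glucose <- rd("glucose")
  if (is.null(glucose) || nrow(glucose) == 0) stop("empty glucose stream at ", prefix)
  rec <- subject_record(
    subject_id = meta$subject_id %||% basename(prefix),
    glucose = glucose, boluses = rd("bolus"), meals = rd("meal"), basal = rd("basal"),
    start_wall = as.POSIXct(meta$start_wall %||% "2021-07-01 00:00:00", tz = "UTC"),
    split = if (!is.null(meta$split)) unlist(meta$split))
  rec$anchored <- isTRUE(meta$anchored)
  rec$interpolated <- isTRUE(meta$interpolated)
  rec
}

write_subject_csv <- function(record, prefix) {
  wr <- function(df, s) utils::write.csv(df, paste0(prefix, "_", s, ".csv"), row.names = FALSE)
  wr(record$glucose, "glucose"); wr(record$boluses, "bolus")
  wr(record$meals, "meal"); wr(record$basal, "basal")
  jsonlite::write_json(list(subject_id = record$subject_id,
                            start_wall = format(record$start_wall, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                            split = record$split, anchored = record$anchored,
                            interpolated = record$interpolated),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
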