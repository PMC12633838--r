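# Input/output for CGM, meal and bolus record streams.
# Canonical internal unit is mmol/L; canonical time is the naive local
# clock stored as POSIXct in UTC (no timezone arithmetic is ever applied).

#' Convert glucose from mg/dL to mmol/L
#'
#' @param value_mgdl Numeric vector of glucose concentrations in mg/dL,
#'   all `>= 0`.
#' @return Numeric vector in mmol/L (`value_mgdl / 18.016`).
#' @examples
#' to_mmol(180.16)  # 10
#' @export
to_mmol <- function(value_mgdl) {
  if (!is.numeric(value_mgdl)) stop("glucose values must be numeric")
  if (any(value_mgdl < 0, na.rm = TRUE)) {
    stop("glucose concentration cannot be negative")
  }
  value_mgdl / GLUCOSE_MGDL_PER_MMOL
}

# Parse timestamps in ISO ("2021-06-07 08:00:00") or day-first OhioT1DM
# ("07-06-2021 08:00:00") layout; returns POSIXct (UTC) with NA for
# unparseable entries.
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  iso <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  iso2 <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  dmy <- as.POSIXct(x, tz = "UTC", format = "%d-%m-%Y %H:%M:%S")
  out[!is.na(iso)] <- iso[!is.na(iso)]
  out[is.na(out) & !is.na(iso2)] <- iso2[is.na(out) & !is.na(iso2)]
  out[is.na(out) & !is.na(dmy)] <- dmy[is.na(out) & !is.na(dmy)]
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

empty_glucose <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
             value = numeric())
}
empty_meals <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
             carbs = numeric(), source = character())
}
empty_boluses <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
             dose = numeric(), kind = character())
}

#' Construct a participant record
#'
#' Bundles one participant's CGM series, meal log and bolus log into the
#' canonical container used by the isolation and clustering stages.  The
#' glucose series is sorted by time and duplicate timestamps are collapsed
#' to the first occurrence (with a warning), so the result is independent
#' of input row order.
#'
#' @param participant_id Opaque identifier string.
#' @param glucose Data frame with columns `timestamp` (POSIXct) and
#'   `value` (mmol/L, all `> 0`).
#' @param meals Data frame with columns `timestamp`, `carbs` (grams, `NA`
#'   when unknown) and `source` (`"reported"` or `"imputed"`).
#' @param boluses Data frame with columns `timestamp`, `dose` (units,
#'   `> 0`) and `kind` (`"unclassified"`, `"meal_related"` or
#'   `"correction"`).
#' @return An object of class `participant_record`: a list with elements
#'   `participant_id`, `glucose`, `meals`, `boluses` and `span` (first and
#'   last calendar day covered by any sample or event).
#' @export
participant_record <- function(participant_id, glucose = empty_glucose(),
                               meals = empty_meals(),
                               boluses = empty_boluses()) {
  stopifnot(is.character(participant_id), length(participant_id) == 1)
  glucose <- as.data.frame(glucose)
  meals <- as.data.frame(meals)
  boluses <- as.data.frame(boluses)
  if (nrow(meals) && is.null(meals$source)) meals$source <- "reported"
  if (nrow(boluses) && is.null(boluses$kind)) boluses$kind <- "unclassified"
  if (!nrow(meals)) meals <- empty_meals()
  if (!nrow(boluses)) boluses <- empty_boluses()

  if (nrow(glucose)) {
    if (any(glucose$value <= 0, na.rm = TRUE)) {
      stop("glucose values must be positive (mmol/L)")
    }
    glucose <- glucose[order(glucose$timestamp), , drop = FALSE]
    dup <- duplicated(glucose$timestamp)
    if (any(dup)) {
      warning(sprintf("%d duplicate CGM timestamp(s) dropped (first kept)",
                      sum(dup)))
      glucose <- glucose[!dup, , drop = FALSE]
    }
  } else {
    glucose <- empty_glucose()
  }
  meals <- meals[order(meals$timestamp), , drop = FALSE]
  boluses <- boluses[order(boluses$timestamp), , drop = FALSE]
  rownames(glucose) <- rownames(meals) <- rownames(boluses) <- NULL

  all_ts <- c(glucose$timestamp, meals$timestamp, boluses$timestamp)
  span <- if (length(all_ts)) {
    as.Date(range(all_ts), tz = "UTC")
  } else {
    as.Date(c(NA, NA))
  }
  structure(list(participant_id = participant_id, glucose = glucose,
                 meals = meals, boluses = boluses, span = span),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf(
    "<participant_record %s>\n  %d CGM samples, %d meals, %d boluses\n",
    x$participant_id, nrow(x$glucose), nrow(x$meals), nrow(x$boluses)))
  if (!is.na(x$span[1])) {
    cat(sprintf("  span %s to %s\n", x$span[1], x$span[2]))
  }
  invisible(x)
}

#' Read an OhioT1DM-style participant XML file
#'
#' Parses a per-participant XML document carrying `glucose_level`, `meal`
#' and `bolus` event streams (each a sequence of `<event>` elements with a
#' `ts` attribute plus `value`, `carbs` or `dose`).  Glucose values are
#' assumed to be mg/dL and are converted to mmol/L.  Records with
#' unparseable timestamps are skipped with a warning and counted in the
#' read report attached as attribute `"read_report"`.
#'
#' @param path Path to the XML file.
#' @return A [participant_record()].
#' @export
read_ohio_xml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XML in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  pid <- xml2::xml_attr(doc, "id")
  if (is.na(pid)) pid <- tools::file_path_sans_ext(basename(path))

  pull_stream <- function(stream, value_attr) {
    nodes <- xml2::xml_find_all(doc, sprintf(".//%s/event", stream))
    ts_raw <- xml2::xml_attr(nodes, "ts")
    # bolus streams sometimes carry ts_begin instead of ts
    alt <- xml2::xml_attr(nodes, "ts_begin")
    ts_raw[is.na(ts_raw)] <- alt[is.na(ts_raw)]
    val <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, value_attr)))
    ts <- parse_timestamp(ts_raw)
    bad <- is.na(ts)
    if (any(bad)) {
      warning(sprintf("%d %s record(s) skipped: unparseable timestamp",
                      sum(bad), stream))
    }
    list(ts = ts[!bad], value = val[!bad], skipped = sum(bad))
  }

  g <- pull_stream("glucose_level", "value")
  m <- pull_stream("meal", "carbs")
  b <- pull_stream("bolus", "dose")

  rec <- participant_record(
    pid,
    glucose = data.frame(timestamp = g$ts, value = to_mmol(g$value)),
    meals = if (length(m$ts)) {
      data.frame(timestamp = m$ts, carbs = m$value, source = "reported")
    } else empty_meals(),
    boluses = if (length(b$ts)) {
      data.frame(timestamp = b$ts, dose = b$value, kind = "unclassified")
    } else empty_boluses())
  attr(rec, "read_report") <- c(glucose_skipped = g$skipped,
                                meal_skipped = m$skipped,
                                bolus_skipped = b$skipped)
  rec
}

#' Read the generic CSV dialect
#'
#' Reads up to three headered CSV files: glucose (`timestamp`, `value`,
#' optional `unit`), meals (`timestamp`, `carbs`, optional `source`) and
#' boluses (`timestamp`, `dose`).  Glucose defaults to mg/dL; a `unit`
#' column equal to `"mmol/L"` suppresses conversion.  Blank carbohydrate
#' cells become unknown (`NA`) carbs.
#'
#' @param glucose_path,meals_path,bolus_path CSV file paths; `meals_path`
#'   and `bolus_path` may be `NULL`.
#' @param participant_id Identifier; defaults to the glucose file stem.
#' @return A [participant_record()].
#' @export
read_events_csv <- function(glucose_path, meals_path = NULL,
                            bolus_path = NULL, participant_id = NULL) {
  need <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s: missing required column(s) %s; expected header (%s)",
                   path, paste(miss, collapse = ", "),
                   paste(cols, collapse = ", ")))
    }
  }
  g <- utils::read.csv(glucose_path, stringsAsFactors = FALSE)
  need(g, c("timestamp", "value"), glucose_path)
  ts <- parse_timestamp(g$timestamp)
  if (any(is.na(ts))) stop(glucose_path, ": unparseable timestamp(s)")
  val <- as.numeric(g$value)
  unit <- if (!is.null(g$unit)) g$unit else rep("mg/dL", nrow(g))
  mgdl <- unit != "mmol/L"
  val[mgdl] <- to_mmol(val[mgdl])
  glucose <- data.frame(timestamp = ts, value = val)

  meals <- empty_meals()
  if (!is.null(meals_path)) {
    m <- utils::read.csv(meals_path, stringsAsFactors = FALSE)
    need(m, c("timestamp", "carbs"), meals_path)
    mts <- parse_timestamp(m$timestamp)
    if (any(is.na(mts))) stop(meals_path, ": unparseable timestamp(s)")
    meals <- data.frame(
      timestamp = mts,
      carbs = suppressWarnings(as.numeric(m$carbs)),
      source = if (!is.null(m$source)) m$source else "reported")
  }
  boluses <- empty_boluses()
  if (!is.null(bolus_path)) {
    b <- utils::read.csv(bolus_path, stringsAsFactors = FALSE)
    need(b, c("timestamp", "dose"), bolus_path)
    bts <- parse_timestamp(b$timestamp)
    if (any(is.na(bts))) stop(bolus_path, ": unparseable timestamp(s)")
    boluses <- data.frame(timestamp = bts, dose = as.numeric(b$dose),
                          kind = "unclassified")
  }
  if (is.null(participant_id)) {
    participant_id <- tools::file_path_sans_ext(basename(glucose_path))
  }
  participant_record(participant_id, glucose, meals, boluses)
}

#' Write a participant record to the generic CSV dialect
#'
#' Emits `<id>_glucose.csv` (with `unit = "mmol/L"` so a re-read does not
#' reconvert), `<id>_meals.csv` and `<id>_boluses.csv` into `dir`.
#' Re-reading with [read_events_csv()] reproduces timestamps exactly and
#' glucose values to printed precision (15 significant digits).
#'
#' @param record A [participant_record()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_participant_csv <- function(record, dir) {
  stopifnot(inherits(record, "participant_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record$participant_id
  paths <- c(
    glucose = file.path(dir, paste0(id, "_glucose.csv")),
    meals = file.path(dir, paste0(id, "_meals.csv")),
    boluses = file.path(dir, paste0(id, "_boluses.csv")))
  g <- data.frame(timestamp = format_timestamp(record$glucose$timestamp),
                  value = format(record$glucose$value, digits = 15,
                                 scientific = FALSE, trim = TRUE),
                  unit = "mmol/L")
  utils::write.csv(g, paths["glucose"], row.names = FALSE)
  m <- data.frame(timestamp = format_timestamp(record$meals$timestamp),
                  carbs = record$meals$carbs, source = record$meals$source)
  utils::write.csv(m, paths["meals"], row.names = FALSE)
  b <- data.frame(timestamp = format_timestamp(record$boluses$timestamp),
                  dose = record$boluses$dose)
  utils::write.csv(b, paths["boluses"], row.names = FALSE)
  invisible(paths)
}

#' Write a participant record in the OhioT1DM-style XML dialect
#'
#' Glucose values are emitted in mg/dL (the dialect's native unit).
#' Intended for tests and for exporting synthetic cohorts; the package
#' never bundles restricted clinical data.
#'
#' @param record A [participant_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ohio_xml <- function(record, path) {
  stopifnot(inherits(record, "participant_record"))
  lines <- c(sprintf('<patient id="%s">', record$participant_id),
             "  <glucose_level>")
  if (nrow(record$glucose)) {
    lines <- c(lines, sprintf('    <event ts="%s" value="%s"/>',
                              format_timestamp(record$glucose$timestamp),
                              format(record$glucose$value *
                                       GLUCOSE_MGDL_PER_MMOL,
                                     digits = 15, scientific = FALSE,
                                     trim = TRUE)))
  }
  lines <- c(lines, "  </glucose_level>", "  <meal>")
  rep_meals <- record$meals[record$meals$source == "reported", , drop = FALSE]
  if (nrow(rep_meals)) {
    carbs <- ifelse(is.na(rep_meals$carbs), "",
                    format(rep_meals$carbs, trim = TRUE))
    lines <- c(lines, sprintf('    <event ts="%s" carbs="%s"/>',
                              format_timestamp(rep_meals$timestamp),
                              carbs))
  }
  lines <- c(lines, "  </meal>", "  <bolus>")
  if (nrow(record$boluses)) {
    lines <- c(lines, sprintf('    <event ts="%s" dose="%s"/>',
                              format_timestamp(record$boluses$timestamp),
                              format(record$boluses$dose, trim = TRUE)))
  }
  lines <- c(lines, "  </bolus>", "</patient>")
  writeLines(lines, path)
  invisible(path)
}
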