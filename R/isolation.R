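# PPGR isolation: meal bands, bolus classification, mealtime imputation,
# 4-hour window extraction with carbohydrate merging and peak centering.

# Meal bands on the local 24-hour clock, half-open [start, end) minutes.
BAND_TABLE <- data.frame(
  band = c("breakfast", "lunch", "snack", "dinner"),
  start_min = c(360, 600, 840, 1080),
  end_min = c(600, 840, 1080, 1320),
  stringsAsFactors = FALSE)

minutes_of_day <- function(ts) {
  as.integer(format(ts, "%H", tz = "UTC")) * 60L +
    as.integer(format(ts, "%M", tz = "UTC"))
}

#' Assign a clock time to a meal band
#'
#' Bands are half-open intervals on the local clock: breakfast
#' \[06:00, 10:00), lunch \[10:00, 14:00), snack \[14:00, 18:00), dinner
#' \[18:00, 22:00).  Times outside 06:00-22:00 belong to no band.
#'
#' @param x POSIXct vector, or character `"HH:MM"` clock times.
#' @return Character vector of band names, `NA` outside all bands.
#' @examples
#' band_of("07:30")  # "breakfast"
#' band_of("10:00")  # "lunch" (left-closed boundary)
#' @export
band_of <- function(x) {
  mins <- if (inherits(x, "POSIXt")) {
    minutes_of_day(x)
  } else {
    parts <- strsplit(as.character(x), ":", fixed = TRUE)
    vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]),
           integer(1))
  }
  out <- rep(NA_character_, length(mins))
  for (i in seq_len(nrow(BAND_TABLE))) {
    hit <- !is.na(mins) & mins >= BAND_TABLE$start_min[i] &
      mins < BAND_TABLE$end_min[i]
    out[hit] <- BAND_TABLE$band[i]
  }
  out
}

#' Classify boluses as meal-related or corrections
#'
#' A bolus is `meal_related` iff some reported meal `m` satisfies
#' `m.timestamp - pre_minutes <= bolus.timestamp <= m.timestamp +
#' window_minutes`; every other bolus is a `correction`.  Idempotent.
#'
#' @param record A [participant_record()].
#' @param window_minutes Post-meal extent of the matching window (240).
#' @param pre_minutes Pre-meal slack of the matching window (4).
#' @return The record with every bolus `kind` set.
#' @export
classify_boluses <- function(record, window_minutes = 240, pre_minutes = 4) {
  stopifnot(inherits(record, "participant_record"))
  b <- record$boluses
  if (!nrow(b)) return(record)
  meals <- record$meals[record$meals$source == "reported", , drop = FALSE]
  kind <- rep("correction", nrow(b))
  if (nrow(meals)) {
    for (i in seq_len(nrow(b))) {
      d_min <- as.numeric(difftime(b$timestamp[i], meals$timestamp,
                                   units = "mins"))
      if (any(d_min >= -pre_minutes & d_min <= window_minutes)) {
        kind[i] <- "meal_related"
      }
    }
  }
  record$boluses$kind <- kind
  record
}

record_week <- function(dates, origin) as.integer(floor(as.numeric(dates - origin) / 7))

#' Impute missing mealtimes from weekday habits
#'
#' For each calendar day and meal band within the record's span that has
#' neither a reported meal nor a meal-related bolus, and for which at
#' least one reported meal exists in the same band on the same weekday of
#' a different week, an imputed meal is emitted at the mean clock time of
#' those matching meals, rounded to the nearest 5-minute grid point.
#' Imputed meals carry unknown carbs.  Boluses are classified first if
#' any are still unclassified.
#'
#' @param record A [participant_record()].
#' @return Data frame of imputed meal events (`timestamp`, `carbs`,
#'   `source = "imputed"`); zero rows when nothing can be imputed.
#' @export
impute_start_times <- function(record) {
  stopifnot(inherits(record, "participant_record"))
  if (any(record$boluses$kind == "unclassified")) {
    record <- classify_boluses(record)
  }
  out <- empty_meals()
  if (is.na(record$span[1])) return(out)
  days <- seq(record$span[1], record$span[2], by = "day")
  if (length(days) < 8) return(out)  # no "other weeks" to draw from

  meals <- record$meals[record$meals$source == "reported", , drop = FALSE]
  meals$band <- band_of(meals$timestamp)
  meals$date <- as.Date(meals$timestamp, tz = "UTC")
  meals$week <- record_week(meals$date, days[1])
  meals$wday <- format(meals$date, "%u")
  mb <- record$boluses[record$boluses$kind == "meal_related", , drop = FALSE]
  mb_band <- band_of(mb$timestamp)
  mb_date <- as.Date(mb$timestamp, tz = "UTC")

  imput <- list()
  for (d in seq_along(days)) {
    date <- days[d]
    wk <- record_week(date, days[1])
    wd <- format(date, "%u")
    for (band in c("breakfast", "lunch", "snack", "dinner")) {
      has_meal <- any(!is.na(meals$band) & meals$band == band &
                        meals$date == date)
      has_bolus <- any(!is.na(mb_band) & mb_band == band & mb_date == date)
      if (has_meal || has_bolus) next
      cand <- meals[!is.na(meals$band) & meals$band == band &
                      meals$wday == wd & meals$week != wk, , drop = FALSE]
      if (!nrow(cand)) next
      clock <- mean(minutes_of_day(cand$timestamp))
      clock <- round(clock / 5) * 5
      imput[[length(imput) + 1]] <- data.frame(
        timestamp = as.POSIXct(paste(date, sprintf("%02d:%02d:00",
                                                   clock %/% 60, clock %% 60)),
                               tz = "UTC"),
        carbs = NA_real_, source = "imputed")
    }
  }
  if (length(imput)) out <- do.call(rbind, imput)
  rownames(out) <- NULL
  out
}

#' Append imputed mealtimes to a record
#'
#' Convenience wrapper: classifies boluses, computes
#' [impute_start_times()] and returns the record with the imputed meals
#' merged into its meal log (sorted by time).
#'
#' @param record A [participant_record()].
#' @return The augmented record.
#' @export
with_imputed_meals <- function(record) {
  record <- classify_boluses(record)
  imp <- impute_start_times(record)
  if (nrow(imp)) {
    record$meals <- rbind(record$meals, imp)
    record$meals <- record$meals[order(record$meals$timestamp), , drop = FALSE]
    rownames(record$meals) <- NULL
  }
  record
}

#' Center a glucose window on its peak
#'
#' Subtracts the in-window maximum from every value, so the returned
#' series attains a maximum of exactly 0.  Missing grid points stay
#' missing.
#'
#' @param glucose Non-empty numeric vector (mmol/L); may contain `NA`.
#' @return Numeric vector of differences from the peak.
#' @export
peak_normalize <- function(glucose) {
  if (!length(glucose) || all(is.na(glucose))) {
    stop("cannot peak-normalize an empty glucose window")
  }
  glucose - max(glucose, na.rm = TRUE)
}

#' Isolate postprandial glycemic response events
#'
#' Converts a participant record into meal-categorized 4-hour PPGR
#' windows.  Candidate starts are reported meals, imputed meals, and
#' meal-related boluses on band-days without any meal; one candidate is
#' kept per band-day (reported meal preferred over mealtime bolus over
#' imputed meal, earliest first).  The window is the half-open 4-hour
#' span from the start, gridded at the CGM cadence; windows with fewer
#' than `min_points` samples are excluded.  Carbohydrates of later
#' same-band intakes inside the window are merged into the event.
#'
#' @param record A [participant_record()] with boluses classified and any
#'   imputation already applied (see [with_imputed_meals()]).
#' @param window_minutes Window length (240).
#' @param cadence_minutes CGM grid spacing (5).
#' @param min_points Minimum retained samples per window (24).
#' @return A list with `events` (a `ppgr_events` data frame: `event_id`,
#'   `participant_id`, `band`, `start`, `n_points`, `carbs_total`,
#'   `origin`, `peak`, plus list columns `glucose` and `normalized`, each
#'   a full-grid vector with `NA` at missing slots) and `report` (an
#'   isolation audit: candidate/isolated/excluded counts, imputed starts,
#'   merged intakes, correction boluses per band).
#' @export
isolate_ppgrs <- function(record, window_minutes = 240, cadence_minutes = 5,
                          min_points = 24) {
  stopifnot(inherits(record, "participant_record"))
  if (any(record$boluses$kind == "unclassified")) {
    record <- classify_boluses(record, window_minutes = window_minutes)
  }
  n_slots <- window_minutes %/% cadence_minutes

  meals <- record$meals
  meals$band <- band_of(meals$timestamp)
  meals$date <- as.Date(meals$timestamp, tz = "UTC")
  mb <- record$boluses[record$boluses$kind == "meal_related", , drop = FALSE]
  mb$band <- band_of(mb$timestamp)
  mb$date <- as.Date(mb$timestamp, tz = "UTC")
  # meal-related boluses only seed a PPGR when their band-day has no meal
  if (nrow(mb)) {
    meal_key <- paste(meals$date, meals$band)
    mb <- mb[!(paste(mb$date, mb$band) %in% meal_key), , drop = FALSE]
  }

  cand <- rbind(
    if (nrow(meals)) data.frame(
      timestamp = meals$timestamp, band = meals$band, date = meals$date,
      carbs = meals$carbs,
      origin = ifelse(meals$source == "imputed", "imputed_meal",
                      "reported_meal"),
      priority = ifelse(meals$source == "imputed", 3L, 1L)),
    if (nrow(mb)) data.frame(
      timestamp = mb$timestamp, band = mb$band, date = mb$date,
      carbs = NA_real_, origin = "mealtime_bolus", priority = 2L))
  if (!is.null(cand)) cand <- cand[!is.na(cand$band), , drop = FALSE]

  report <- list(candidates = 0L, isolated = 0L, excluded = 0L,
                 imputed_starts = 0L, merged_intakes = 0L,
                 correction_boluses = table(factor(
                   band_of(record$boluses$timestamp[
                     record$boluses$kind == "correction"]),
                   levels = BAND_TABLE$band)))
  empty_events <- structure(
    data.frame(event_id = character(), participant_id = character(),
               band = character(),
               start = as.POSIXct(character(), tz = "UTC"),
               n_points = integer(), carbs_total = numeric(),
               origin = character(), peak = numeric()),
    class = c("ppgr_events", "data.frame"))
  empty_events$glucose <- list()
  empty_events$normalized <- list()
  if (is.null(cand) || !nrow(cand) || !nrow(record$glucose)) {
    if (!is.null(cand)) report$candidates <- 0L
    return(list(events = empty_events, report = report))
  }

  # one candidate per band-day: highest priority class, then earliest
  cand <- cand[order(cand$date, cand$band, cand$priority, cand$timestamp), ,
               drop = FALSE]
  cand <- cand[!duplicated(paste(cand$date, cand$band)), , drop = FALSE]
  cand <- cand[order(cand$timestamp), , drop = FALSE]
  report$candidates <- nrow(cand)

  gts <- record$glucose$timestamp
  gval <- record$glucose$value
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    start <- cand$timestamp[i]
    off <- as.numeric(difftime(gts, start, units = "mins"))
    in_win <- off >= 0 & off < window_minutes
    slot <- as.integer(round(off[in_win] / cadence_minutes))
    vals <- gval[in_win]
    keep <- slot >= 0 & slot < n_slots & !duplicated(slot)
    slot <- slot[keep]; vals <- vals[keep]
    vec <- rep(NA_real_, n_slots)
    vec[slot + 1L] <- vals
    n_pts <- sum(!is.na(vec))
    if (n_pts < min_points) {
      report$excluded <- report$excluded + 1L
      next
    }
    if (cand$origin[i] == "imputed_meal") report$imputed_starts <-
        report$imputed_starts + 1L

    carbs_known <- if (!is.na(cand$carbs[i])) cand$carbs[i] else numeric()
    later <- meals[!is.na(meals$band) & meals$band == cand$band[i] &
                     meals$timestamp > start &
                     as.numeric(difftime(meals$timestamp, start,
                                         units = "mins")) < window_minutes &
                     meals$source == "reported", , drop = FALSE]
    if (nrow(later)) {
      report$merged_intakes <- report$merged_intakes + nrow(later)
      carbs_known <- c(carbs_known, later$carbs[!is.na(later$carbs)])
    }
    carbs_total <- if (cand$origin[i] == "imputed_meal" ||
                       !length(carbs_known)) NA_real_ else sum(carbs_known)

    peak <- max(vec, na.rm = TRUE)
    rows[[i]] <- list(
      event_id = sprintf("%s_%s_%s", record$participant_id,
                         format(start, "%Y%m%d_%H%M", tz = "UTC"),
                         cand$band[i]),
      participant_id = record$participant_id, band = cand$band[i],
      start = start, n_points = n_pts, carbs_total = carbs_total,
      origin = cand$origin[i], peak = peak, glucose = vec,
      normalized = vec - peak)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  report$isolated <- length(rows)
  if (!length(rows)) return(list(events = empty_events, report = report))

  events <- data.frame(
    event_id = vapply(rows, `[[`, character(1), "event_id"),
    participant_id = record$participant_id,
    band = vapply(rows, `[[`, character(1), "band"),
    start = as.POSIXct(vapply(rows, function(r) as.numeric(r$start),
                              numeric(1)),
                       origin = "1970-01-01", tz = "UTC"),
    n_points = vapply(rows, `[[`, integer(1), "n_points"),
    carbs_total = vapply(rows, `[[`, numeric(1), "carbs_total"),
    origin = vapply(rows, `[[`, character(1), "origin"),
    peak = vapply(rows, `[[`, numeric(1), "peak"))
  events$glucose <- lapply(rows, `[[`, "glucose")
  events$normalized <- lapply(rows, `[[`, "normalized")
  class(events) <- c("ppgr_events", "data.frame")
  list(events = events, report = report)
}

#' @export
print.ppgr_events <- function(x, ...) {
  cat(sprintf("<ppgr_events: %d events>\n", nrow(x)))
  if (nrow(x)) print(table(x$band))
  invisible(x)
}
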