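# Shared fixtures and independent oracles for the test suite.
# Everything is built in code; no binary fixtures.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Build a ppgr_events frame from raw glucose vectors (one event per
# vector), all in one band, one event per day so band-day dedup never
# interferes.  Events are constructed directly, bypassing isolation.
make_events <- function(vlist, band = "lunch", pid = "P1",
                        start0 = "2021-06-07 12:00:00", carbs = NULL) {
  n <- length(vlist)
  starts <- ts_utc(start0) + 86400 * (seq_len(n) - 1)
  ev <- data.frame(
    event_id = sprintf("E%02d", seq_len(n)),
    participant_id = pid, band = band, start = starts,
    n_points = vapply(vlist, function(v) sum(!is.na(v)), integer(1)),
    carbs_total = if (is.null(carbs)) NA_real_ else carbs,
    origin = "reported_meal",
    peak = vapply(vlist, function(v) max(v, na.rm = TRUE), numeric(1)))
  ev$glucose <- lapply(vlist, as.numeric)
  ev$normalized <- lapply(vlist, function(v) v - max(v, na.rm = TRUE))
  class(ev) <- c("ppgr_events", "data.frame")
  ev
}

# A gap-free CGM day grid (288 samples at 5 minutes) at a flat level.
flat_glucose_day <- function(date = "2021-06-07", level = 6) {
  grid <- seq(ts_utc(paste(date, "00:00:00")),
              ts_utc(paste(date, "23:55:00")), by = 300)
  data.frame(timestamp = grid, value = level)
}

make_record <- function(pid = "P1", glucose, meals = NULL, boluses = NULL) {
  participant_record(pid, glucose = glucose,
                     meals = if (is.null(meals)) {
                       data.frame(timestamp = ts_utc(character()),
                                  carbs = numeric(), source = character())
                     } else meals,
                     boluses = if (is.null(boluses)) {
                       data.frame(timestamp = ts_utc(character()),
                                  dose = numeric(), kind = character())
                     } else boluses)
}

# Write an OhioT1DM-style XML fixture from mg/dL readings.
write_xml_fixture <- function(path, readings_mgdl, ts0 = "2021-06-07 00:00:00",
                              meals = NULL, boluses = NULL, id = "P9",
                              bad_ts = 0) {
  ts <- ts_utc(ts0) + 300 * (seq_along(readings_mgdl) - 1)
  lines <- c(sprintf('<patient id="%s">', id), "  <glucose_level>")
  if (length(readings_mgdl)) {
    lines <- c(lines, sprintf('    <event ts="%s" value="%s"/>',
                              format(ts, "%d-%m-%Y %H:%M:%S", tz = "UTC"),
                              readings_mgdl))
  }
  if (bad_ts > 0) {
    lines <- c(lines, rep('    <event ts="not-a-time" value="100"/>', bad_ts))
  }
  lines <- c(lines, "  </glucose_level>", "  <meal>")
  if (!is.null(meals)) {
    lines <- c(lines, sprintf('    <event ts="%s" carbs="%s"/>',
                              format(meals$timestamp, "%d-%m-%Y %H:%M:%S",
                                     tz = "UTC"),
                              meals$carbs))
  }
  lines <- c(lines, "  </meal>", "  <bolus>")
  if (!is.null(boluses)) {
    lines <- c(lines, sprintf('    <event ts="%s" dose="%s"/>',
                              format(boluses$timestamp, "%d-%m-%Y %H:%M:%S",
                                     tz = "UTC"),
                              boluses$dose))
  }
  lines <- c(lines, "  </bolus>", "</patient>")
  writeLines(lines, path)
  path
}

# ---- exhaustive clustering oracle ----------------------------------

# All set partitions of 1..n (Bell(6) = 203, so n <= 6 stays tiny).
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(as.integer(n)))
  }
  out
}

# Enumerate every partition of the events, keep those whose multi-member
# blocks all satisfy the pooled CV constraint (plain sd() route,
# independent of the package's incremental-sums implementation), and
# report the maximal number of assigned (non-singleton) events plus the
# signatures of all partitions attaining it.
oracle_best_partition <- function(vlist, threshold = 36) {
  mu <- mean(unlist(vlist), na.rm = TRUE)
  block_cv <- function(idx) {
    vals <- unlist(vlist[idx])
    vals <- vals[!is.na(vals)]
    100 * stats::sd(vals) / mu
  }
  best <- -1L
  sigs <- character()
  for (p in set_partitions(length(vlist))) {
    blocks <- p[lengths(p) >= 2]
    if (length(blocks) &&
        !all(vapply(blocks, function(b) block_cv(b) < threshold,
                    logical(1)))) next
    assigned <- sum(lengths(blocks))
    sig <- paste(sort(vapply(blocks, function(b)
      paste(sort(b), collapse = ","), character(1))), collapse = ";")
    if (assigned > best) {
      best <- assigned
      sigs <- sig
    } else if (assigned == best) {
      sigs <- union(sigs, sig)
    }
  }
  list(max_assigned = best, signatures = sigs)
}

# Partition signature of a greedy cluster_set, in make_events index space.
greedy_signature <- function(cs, events) {
  blocks <- vapply(cs$clusters, function(cl) {
    paste(sort(match(cl$member_ids, events$event_id)), collapse = ",")
  }, character(1))
  paste(sort(blocks), collapse = ";")
}

# ---- pair-counting adjusted Rand index oracle ----------------------

ari_pair_counting <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[lower.tri(diag(n))]
  same_b <- outer(b, b, "==")[lower.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  total <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == expected) return(1)  # degenerate: both partitions trivial
  (n11 - expected) / (max_idx - expected)
}
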