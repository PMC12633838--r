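# Synthetic CGM cohorts with planted per-band response templates.
#
# Each meal band of a simulated participant owns a small library of
# response templates (baseline, excursion amplitude, time to peak, decay
# half-life); every band-day draws one template, so the true cluster
# structure of the isolated PPGRs is known and recovery can be scored.

NOMINAL_MEALTIMES <- c(breakfast = "07:30", lunch = "12:00",
                       snack = "15:30", dinner = "18:30")

#' Construct a PPGR response template
#'
#' @param template_id Identifier string.
#' @param band Meal band the template belongs to.
#' @param baseline Pre-meal glucose, mmol/L (> 0).
#' @param amplitude Excursion height above baseline, mmol/L (>= 0).
#' @param time_to_peak Minutes from meal to peak (15-120).
#' @param decay_halflife Post-peak exponential half-life, minutes.
#' @param carb_mean,carb_sd Carbohydrate distribution of meals drawn from
#'   this template, grams.
#' @return One-row data frame describing the template.
#' @export
response_template <- function(template_id, band, baseline, amplitude,
                              time_to_peak, decay_halflife,
                              carb_mean, carb_sd) {
  stopifnot(baseline > 0, amplitude >= 0,
            time_to_peak >= 15, time_to_peak <= 120,
            decay_halflife > 0, carb_mean >= 0, carb_sd >= 0)
  data.frame(template_id = template_id, band = band, baseline = baseline,
             amplitude = amplitude, time_to_peak = time_to_peak,
             decay_halflife = decay_halflife, carb_mean = carb_mean,
             carb_sd = carb_sd, stringsAsFactors = FALSE)
}

#' Default well-separated template library
#'
#' Builds `k` templates per band whose baselines are spread far enough
#' apart that same-template event pairs always satisfy the 36% pooled-CV
#' constraint while cross-template pairs violate it.  With two templates
#' the baselines (2.5 and 16 mmol/L) keep foreign single-event additions
#' blocked for clusters of up to ~13 members; with three templates the
#' positivity of glucose caps how far apart adjacent levels can sit
#' relative to the category mean, so exact recovery is only guaranteed
#' for very small categories (see the methods vignette).
#'
#' @param bands Character vector of bands to cover.
#' @param k Templates per band (1-6).
#' @return Data frame of stacked [response_template()] rows.
#' @export
default_templates <- function(bands = c("breakfast", "lunch", "dinner"),
                              k = 2) {
  stopifnot(k >= 1, k <= 6)
  base_levels <- switch(as.character(k),
                        "1" = 6.5,
                        "2" = c(2.5, 16),
                        "3" = c(2.5, 9.25, 16),
                        seq(2.5, 18, length.out = k))
  do.call(rbind, lapply(bands, function(b) {
    do.call(rbind, lapply(seq_len(k), function(i) {
      response_template(sprintf("%s_T%d", b, i), b,
                        baseline = base_levels[i], amplitude = 1.2,
                        time_to_peak = 45, decay_halflife = 45,
                        carb_mean = 30 + 30 * (i - 1), carb_sd = 8)
    }))
  }))
}

#' Simulation configuration
#'
#' @param participants Number of participants.
#' @param weeks Record span in weeks (default 8, the usual CGM study
#'   span emulated here).
#' @param templates_per_band Planted templates per meal band (1-6),
#'   ignored when `templates` is supplied.
#' @param noise_sd I.i.d. Gaussian sensor noise SD, mmol/L.
#' @param mealtime_jitter Max mealtime deviation from the band's nominal
#'   time, minutes (drawn uniformly in 5-minute steps).
#' @param p_missing_mealtime Probability a meal log is suppressed (the
#'   glucose trace and its bolus are kept, exercising imputation).
#' @param p_sensor_dropout Per-day probability of deleting a contiguous
#'   CGM sample run (exercising the minimum-points filter).
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @param include_snack Also simulate snack-band meals (default FALSE).
#' @param baseline_glucose Between-meal glucose level, mmol/L.
#' @param templates Optional template data frame (see
#'   [default_templates()]).
#' @param start_date First day of the record (a Monday by default).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(participants = 1, weeks = 8, templates_per_band = 2,
                       noise_sd = 0.25, mealtime_jitter = 15,
                       p_missing_mealtime = 0.1, p_sensor_dropout = 0.05,
                       seed, include_snack = FALSE, baseline_glucose = 6,
                       templates = NULL, start_date = "2021-06-07") {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(participants >= 1, weeks >= 1, noise_sd >= 0,
            mealtime_jitter >= 0,
            p_missing_mealtime >= 0, p_missing_mealtime <= 1,
            p_sensor_dropout >= 0, p_sensor_dropout <= 1,
            baseline_glucose > 0)
  bands <- c("breakfast", "lunch", if (include_snack) "snack", "dinner")
  if (is.null(templates)) {
    templates <- default_templates(bands, templates_per_band)
  }
  structure(list(participants = as.integer(participants),
                 weeks = as.integer(weeks),
                 noise_sd = noise_sd, mealtime_jitter = mealtime_jitter,
                 p_missing_mealtime = p_missing_mealtime,
                 p_sensor_dropout = p_sensor_dropout,
                 seed = as.integer(seed), include_snack = include_snack,
                 baseline_glucose = baseline_glucose, bands = bands,
                 templates = templates,
                 start_date = as.Date(start_date)),
            class = "sim_config")
}

#' Evaluate a response template on the window grid
#'
#' Linear rise from baseline to `baseline + amplitude` at
#' `time_to_peak`, then exponential decay back toward baseline with the
#' template's half-life: the value at `time_to_peak + decay_halflife` is
#' `baseline + amplitude/2`.
#'
#' @param template One-row template data frame.
#' @param offsets Minutes from the meal (default the 48-point 4-hour
#'   grid, 0 to 235 by 5).
#' @return Glucose vector, mmol/L.
#' @export
template_curve <- function(template, offsets = seq(0, 235, by = 5)) {
  ttp <- template$time_to_peak
  hl <- template$decay_halflife
  kernel <- ifelse(offsets <= ttp, offsets / ttp,
                   0.5^((offsets - ttp) / hl))
  template$baseline + template$amplitude * kernel
}

#' Simulate one participant with known cluster structure
#'
#' Lays a full 5-minute CGM grid over the configured span at the
#' baseline glucose level, overwrites each band-day's 4-hour post-meal
#' segment with a randomly drawn template curve, adds i.i.d. Gaussian
#' sensor noise everywhere, draws per-meal carbs from the template's
#' distribution (truncated at zero), emits a matching bolus for every
#' meal, suppresses meal logs with the configured probability (the bolus
#' is kept and, lacking a nearby logged meal, classifies as a
#' correction, so the band-day becomes imputable), and deletes
#' contiguous sample runs to emulate sensor dropouts.  Mealtimes sit on
#' the 5-minute grid.  Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @param index Participant index (1-based); the RNG stream is seeded
#'   with `seed + index` so participants are independent and stable.
#' @return List with `record` (a [participant_record()]) and `truth` (a
#'   data frame: `date`, `band`, `mealtime`, `template_id`, `carbs`,
#'   `logged`).
#' @export
simulate_participant <- function(config, index = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + index, {
    days <- seq(config$start_date, by = "day",
                length.out = config$weeks * 7)
    grid <- seq(as.POSIXct(paste(days[1], "00:00:00"), tz = "UTC"),
                as.POSIXct(paste(days[length(days)], "23:55:00"), tz = "UTC"),
                by = 300)
    gval <- config$baseline_glucose +
      stats::rnorm(length(grid), 0, config$noise_sd)

    jit_steps <- if (config$mealtime_jitter >= 5) {
      seq(-5 * (config$mealtime_jitter %/% 5),
          5 * (config$mealtime_jitter %/% 5), by = 5)
    } else 0
    offs <- seq(0, 235, by = 5)

    # Balanced menu rotation: each band's template sequence is a seeded
    # permutation of an evenly stocked multiset, emulating a habitual
    # meal repertoire cycled over the study span (and keeping planted
    # cluster sizes near-equal, which the recovery analysis relies on).
    tpl_seq <- lapply(config$bands, function(band) {
      k <- sum(config$templates$band == band)
      sample(rep(seq_len(k), length.out = length(days)))
    })
    names(tpl_seq) <- config$bands

    truth <- list(); meal_rows <- list(); bolus_rows <- list()
    for (d in seq_along(days)) {
      for (band in config$bands) {
        tpls <- config$templates[config$templates$band == band, ,
                                 drop = FALSE]
        tpl <- tpls[tpl_seq[[band]][d], , drop = FALSE]
        jitter <- if (length(jit_steps) > 1) sample(jit_steps, 1) else 0
        mealtime <- as.POSIXct(
          paste(days[d], paste0(NOMINAL_MEALTIMES[[band]], ":00")),
          tz = "UTC") + 60 * jitter
        curve <- template_curve(tpl, offs) +
          stats::rnorm(length(offs), 0, config$noise_sd)
        idx <- match(as.numeric(mealtime) + 60 * offs, as.numeric(grid))
        ok <- !is.na(idx)
        gval[idx[ok]] <- curve[ok]
        carbs <- max(0, round(stats::rnorm(1, tpl$carb_mean, tpl$carb_sd)))
        logged <- stats::runif(1) >= config$p_missing_mealtime
        truth[[length(truth) + 1]] <- data.frame(
          date = days[d], band = band, mealtime = mealtime,
          template_id = tpl$template_id, carbs = carbs, logged = logged)
        if (logged) {
          meal_rows[[length(meal_rows) + 1]] <- data.frame(
            timestamp = mealtime, carbs = carbs, source = "reported")
        }
        bolus_rows[[length(bolus_rows) + 1]] <- data.frame(
          timestamp = mealtime, dose = max(0.5, round(carbs / 10, 1)),
          kind = "unclassified")
      }
    }

    keep <- rep(TRUE, length(grid))
    if (config$p_sensor_dropout > 0) {
      per_day <- 288L
      for (d in seq_along(days)) {
        if (stats::runif(1) < config$p_sensor_dropout) {
          len <- sample(30:60, 1)
          at <- (d - 1L) * per_day + sample.int(per_day, 1)
          keep[at:min(at + len - 1L, length(grid))] <- FALSE
        }
      }
    }
    gval <- pmax(gval, 0.1)  # glucose must stay positive

    record <- participant_record(
      sprintf("S%02d", index),
      glucose = data.frame(timestamp = grid[keep], value = gval[keep]),
      meals = if (length(meal_rows)) do.call(rbind, meal_rows)
              else empty_meals(),
      boluses = if (length(bolus_rows)) do.call(rbind, bolus_rows)
                else empty_boluses())
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(record = record, truth = truth)
  })
}

#' Simulate a cohort
#'
#' @param config A [sim_config()].
#' @return List of `simulate_participant()` results, one per participant.
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$participants), function(i) {
    simulate_participant(config, i)
  })
}

#' Planted template labels for isolated events
#'
#' Matches each event to the simulation truth by calendar day and meal
#' band (robust to jitter and to imputed start times).
#'
#' @param truth Truth data frame from [simulate_participant()].
#' @param events A `ppgr_events` data frame.
#' @return Character vector of template ids aligned with `events` rows
#'   (`NA` where no truth row matches).
#' @export
truth_labels <- function(truth, events) {
  key_t <- paste(truth$date, truth$band)
  key_e <- paste(as.Date(events$start, tz = "UTC"), events$band)
  truth$template_id[match(key_e, key_t)]
}

#' Score cluster recovery against the planted truth
#'
#' Adjusted Rand index between planted template labels and the cluster
#' assignment (the outlier group counts as one label of its own).
#'
#' @param truth Truth data frame from [simulate_participant()].
#' @param clusterset A `cluster_set`.
#' @param events The `ppgr_events` the cluster set was built from.
#' @return Agreement in \[-1, 1\]; 1 is perfect recovery.
#' @export
recovery_score <- function(truth, clusterset, events) {
  asg <- cluster_assignments(clusterset)
  idx <- match(asg$event_id, events$event_id)
  labels_true <- truth_labels(truth, events[idx, , drop = FALSE])
  keep <- !is.na(labels_true)
  if (!sum(keep)) stop("no clustered event matches the truth table")
  mclust::adjustedRandIndex(labels_true[keep], asg$cluster[keep])
}
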