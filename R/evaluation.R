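# Cluster evaluation: per-cluster dispersion metrics, per-offset mean
# curves, and the per-participant report table.

events_by_id <- function(events, ids) {
  events[match(ids, events$event_id), , drop = FALSE]
}

sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else
  if (length(x) == 1) 0 else NA_real_

#' Evaluate one cluster
#'
#' Computes the dispersion metrics of a cluster: the sample standard
#' deviation of its pooled member glucose values, the standard error
#' (SD divided by the square root of the number of member events), the
#' internal CV (pooled CV against the meal-category mean), peak and
#' carbohydrate summaries, and the comparison of the SE with the CGM
#' sensor error.
#'
#' @param cluster A cluster element of a `cluster_set` (or its outlier
#'   group).
#' @param events The `ppgr_events` of the category (members are looked
#'   up by id).
#' @param context The category's `meal_context`.
#' @param sensor_error CGM reference error in mmol/L (default 0.8).
#' @return One-row data frame: `cluster_id`, `n_events`, `sd`, `se`,
#'   `internal_cv`, `peak_mean`, `peak_sd`, `carbs_mean`, `carbs_sd`,
#'   `n_carb_known`, `se_below_sensor_error`, `is_outlier_group`.
#' @export
cluster_metrics <- function(cluster, events, context,
                            sensor_error = DEFAULT_SENSOR_ERROR) {
  ids <- cluster$member_ids
  if (!length(ids)) stop("cluster_metrics needs a non-empty cluster")
  mem <- events_by_id(events, ids)
  pooled <- unlist(mem$glucose)
  pooled <- pooled[!is.na(pooled)]
  sd_p <- stats::sd(pooled)
  n_ev <- length(ids)
  se <- sd_p / sqrt(n_ev)
  carbs <- mem$carbs_total[!is.na(mem$carbs_total)]
  data.frame(
    cluster_id = as.character(cluster$cluster_id),
    n_events = n_ev,
    sd = sd_p,
    se = se,
    internal_cv = pooled_cv(mem, context),
    peak_mean = mean(mem$peak),
    peak_sd = sd_or_na(mem$peak),
    carbs_mean = if (length(carbs)) mean(carbs) else NA_real_,
    carbs_sd = sd_or_na(carbs),
    n_carb_known = length(carbs),
    se_below_sensor_error = se < sensor_error,
    is_outlier_group = isTRUE(cluster$is_outlier_group))
}

#' Per-offset mean curve of a cluster
#'
#' Aligns member events on their 5-minute offsets from the event start
#' (0 to 235 minutes for a 4-hour window) and computes, at each offset,
#' the mean, SD and SE (SD over the square root of the number of events
#' contributing a value at that offset) across members.
#'
#' @param cluster A cluster element of a `cluster_set`.
#' @param events The category's `ppgr_events`.
#' @param cadence_minutes Grid spacing (5).
#' @param sensor_error CGM reference error echoed into the result (0.8).
#' @return Data frame with columns `offset_minutes`, `mean`, `sd`, `se`,
#'   `n`, `sensor_error`.
#' @export
cluster_curve <- function(cluster, events, cadence_minutes = 5,
                          sensor_error = DEFAULT_SENSOR_ERROR) {
  mem <- events_by_id(events, cluster$member_ids)
  mat <- do.call(rbind, mem$glucose)  # events x offsets
  n_off <- ncol(mat)
  n <- colSums(!is.na(mat))
  mu <- ifelse(n > 0, colMeans(mat, na.rm = TRUE), NA_real_)
  sdv <- apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2) stats::sd(col) else if (length(col) == 1) 0 else NA_real_
  })
  data.frame(offset_minutes = (seq_len(n_off) - 1L) * cadence_minutes,
             mean = mu, sd = sdv,
             se = ifelse(n > 0, sdv / sqrt(n), NA_real_),
             n = n, sensor_error = sensor_error)
}

#' Per-participant, per-band report table
#'
#' One row per meal band mirroring the clinical report layout: number of
#' clusters formed; mean (SD) across non-outlier clusters of events per
#' cluster, cluster peak glucose, internal cluster CV and known-carb
#' intake; the outlier-group size and metrics in dedicated columns; and
#' the carbohydrate one-way ANOVA (F, dfs, p) or its skip reason.
#'
#' @param clustersets Named list of `cluster_set` objects (one per band)
#'   for a single participant.
#' @param events The participant's full `ppgr_events`.
#' @param sensor_error CGM reference error in mmol/L (0.8).
#' @return Data frame with one row per band.
#' @export
participant_summary <- function(clustersets, events,
                                sensor_error = DEFAULT_SENSOR_ERROR) {
  rows <- lapply(clustersets, function(cs) {
    band <- if (!is.null(cs$context)) cs$context$band else NA_character_
    pid <- if (!is.null(cs$context)) cs$context$participant_id else
      unique(events$participant_id)[1]
    base <- data.frame(
      participant_id = pid, band = band,
      n_events = length(unlist(lapply(cs$clusters, `[[`, "member_ids"))) +
        length(cs$outliers$member_ids),
      n_clusters = length(cs$clusters),
      events_per_cluster_mean = NA_real_, events_per_cluster_sd = NA_real_,
      peak_mean = NA_real_, peak_sd = NA_real_,
      internal_cv_mean = NA_real_, internal_cv_sd = NA_real_,
      carbs_mean = NA_real_, carbs_sd = NA_real_,
      outlier_n = length(cs$outliers$member_ids),
      outlier_peak_mean = NA_real_, outlier_peak_sd = NA_real_,
      outlier_cv = NA_real_,
      outlier_carbs_mean = NA_real_, outlier_carbs_sd = NA_real_,
      anova_f = NA_real_, anova_df1 = NA_integer_, anova_df2 = NA_integer_,
      anova_p = NA_real_, anova_skip = NA_character_)
    if (is.null(cs$context)) {
      base$anova_skip <- "no events"
      return(base)
    }
    band_events <- events[events$band == band, , drop = FALSE]
    ctx <- cs$context
    if (length(cs$clusters)) {
      met <- do.call(rbind, lapply(cs$clusters, cluster_metrics,
                                   events = band_events, context = ctx,
                                   sensor_error = sensor_error))
      # the reporting invariant: committed clusters stay under threshold
      stopifnot(all(met$internal_cv < cs$threshold))
      base$events_per_cluster_mean <- mean(met$n_events)
      base$events_per_cluster_sd <- sd_or_na(met$n_events)
      base$peak_mean <- mean(met$peak_mean)
      base$peak_sd <- sd_or_na(met$peak_mean)
      base$internal_cv_mean <- mean(met$internal_cv)
      base$internal_cv_sd <- sd_or_na(met$internal_cv)
      known <- met$carbs_mean[!is.na(met$carbs_mean)]
      base$carbs_mean <- if (length(known)) mean(known) else NA_real_
      base$carbs_sd <- sd_or_na(known)
    }
    if (length(cs$outliers$member_ids)) {
      om <- cluster_metrics(cs$outliers, band_events, ctx, sensor_error)
      base$outlier_peak_mean <- om$peak_mean
      base$outlier_peak_sd <- om$peak_sd
      base$outlier_cv <- om$internal_cv
      base$outlier_carbs_mean <- om$carbs_mean
      base$outlier_carbs_sd <- om$carbs_sd
    }
    an <- carb_cluster_test(cs, band_events)
    if (inherits(an, "anova_skip")) {
      base$anova_skip <- an$reason
    } else {
      base$anova_f <- an$f_stat
      base$anova_df1 <- an$df_between
      base$anova_df2 <- an$df_within
      base$anova_p <- an$p_value
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
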