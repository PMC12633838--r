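# End-to-end orchestration: simulate/read -> isolate -> cluster ->
# evaluate -> test, with CSV outputs and a JSON run manifest.

PIPELINE_DEFAULTS <- list(
  threshold = 36, window_minutes = 240, cadence_minutes = 5,
  min_points = 24, sensor_error = 0.8, bolus_pre_minutes = 4,
  include_snack = FALSE)

#' Validate a pipeline configuration
#'
#' Accepts a configuration list (or a YAML/JSON file path), applies the
#' documented defaults (threshold 36, window 240 min, cadence 5 min,
#' min_points 24, sensor_error 0.8 mmol/L, bolus_pre_minutes 4,
#' include_snack FALSE), and rejects unknown keys and invalid values
#' with an itemized report.
#'
#' The `input` section must contain exactly one of:
#' * `xml`: character vector of OhioT1DM-style XML paths,
#' * `csv`: list of lists with `glucose` (required), `meals`, `bolus`,
#' * `simulate`: arguments for [sim_config()] (seed required).
#'
#' @param config List, or path to a YAML/JSON config file.
#' @return Validated configuration list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("input", "out_dir", names(PIPELINE_DEFAULTS))
  problems <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  if (is.null(config$input)) {
    problems <- c(problems, "missing required section: input")
  } else {
    modes <- intersect(names(config$input), c("xml", "csv", "simulate"))
    if (length(modes) != 1) {
      problems <- c(problems,
                    "input must contain exactly one of: xml, csv, simulate")
    }
  }
  for (key in names(PIPELINE_DEFAULTS)) {
    if (is.null(config[[key]])) config[[key]] <- PIPELINE_DEFAULTS[[key]]
  }
  num_keys <- c("threshold", "window_minutes", "cadence_minutes",
                "min_points", "sensor_error", "bolus_pre_minutes")
  for (key in num_keys) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      problems <- c(problems, sprintf("%s must be a single positive number",
                                      key))
    }
  }
  if (!is.logical(config$include_snack) || length(config$include_snack) != 1) {
    problems <- c(problems, "include_snack must be TRUE or FALSE")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(config, class = c("run_config", "list"))
}

load_inputs <- function(config) {
  inp <- config$input
  if (!is.null(inp$simulate)) {
    sim <- do.call(sim_config, inp$simulate)
    res <- simulate_cohort(sim)
    list(records = lapply(res, `[[`, "record"),
         truths = lapply(res, `[[`, "truth"))
  } else if (!is.null(inp$xml)) {
    for (p in inp$xml) if (!file.exists(p)) stop("unreadable input: ", p)
    list(records = lapply(inp$xml, read_ohio_xml), truths = NULL)
  } else {
    recs <- lapply(inp$csv, function(spec) {
      if (is.null(spec$glucose)) stop("csv input needs a glucose path")
      for (p in unlist(spec)) if (!file.exists(p)) {
        stop("unreadable input: ", p)
      }
      read_events_csv(spec$glucose, spec$meals, spec$bolus,
                      participant_id = spec$participant_id)
    })
    list(records = recs, truths = NULL)
  }
}

#' Run the full PPGR clustering pipeline
#'
#' Reads (or simulates) participant records, classifies boluses, imputes
#' missing mealtimes, isolates PPGR events, clusters each participant x
#' band under the CV threshold, evaluates clusters, runs the
#' carbohydrate ANOVA, and writes the full set of output tables plus a
#' JSON manifest into `out_dir`:
#' `events.csv`, `event_curves.csv`, `assignments.csv`,
#' `cluster_summary.csv`, `cluster_curves.csv`, `participant_summary.csv`,
#' `anova.csv`, `manifest.json` (and `truth.csv` for simulated input).
#' Snack-band events are isolated but excluded from clustering and
#' reporting unless `include_snack` is set.
#'
#' @param config A config list, `run_config`, or YAML path (see
#'   [validate_config()]).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("an output directory is required (out_dir)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ppgrclust")),
    config = config[setdiff(names(config), "input")],
    input_mode = intersect(names(config$input), c("xml", "csv", "simulate")),
    started = format_timestamp(Sys.time()), status = "failed",
    participants = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  on.exit(write_manifest())

  inputs <- load_inputs(config)
  report_bands <- c("breakfast", "lunch", "dinner",
                    if (config$include_snack) "snack")

  ev_tabs <- list(); curve_tabs <- list(); asg_tabs <- list()
  clsum_tabs <- list(); ccurve_tabs <- list(); psum_tabs <- list()
  anova_tabs <- list(); truth_tabs <- list()

  for (i in seq_along(inputs$records)) {
    rec <- inputs$records[[i]]
    rec <- classify_boluses(rec, window_minutes = config$window_minutes,
                            pre_minutes = config$bolus_pre_minutes)
    rec <- with_imputed_meals(rec)
    iso <- isolate_ppgrs(rec, window_minutes = config$window_minutes,
                         cadence_minutes = config$cadence_minutes,
                         min_points = config$min_points)
    events <- iso$events
    pid <- rec$participant_id

    ev_tabs[[i]] <- data.frame(
      participant_id = events$participant_id, event_id = events$event_id,
      band = events$band, start = format_timestamp(events$start),
      n_points = events$n_points, carbs_total = events$carbs_total,
      origin = events$origin, peak = events$peak)
    if (nrow(events)) {
      curve_tabs[[i]] <- do.call(rbind, lapply(seq_len(nrow(events)),
        function(j) data.frame(
          event_id = events$event_id[j],
          offset_minutes = (seq_along(events$glucose[[j]]) - 1L) *
            config$cadence_minutes,
          glucose_mmol = events$glucose[[j]],
          normalized = events$normalized[[j]])))
    }

    use <- events[events$band %in% report_bands, , drop = FALSE]
    clustersets <- list()
    for (band in report_bands) {
      be <- use[use$band == band, , drop = FALSE]
      cs <- cluster_category(be, threshold = config$threshold)
      clustersets[[band]] <- cs
      if (!nrow(be)) next
      asg <- cluster_assignments(cs)
      asg_tabs[[length(asg_tabs) + 1]] <- data.frame(
        participant_id = pid, band = band, asg)
      groups <- c(cs$clusters,
                  if (length(cs$outliers$member_ids)) list(cs$outliers))
      for (cl in groups) {
        met <- cluster_metrics(cl, be, cs$context,
                               sensor_error = config$sensor_error)
        clsum_tabs[[length(clsum_tabs) + 1]] <- data.frame(
          participant_id = pid, band = band, met)
        if (!isTRUE(cl$is_outlier_group)) {
          cc <- cluster_curve(cl, be, config$cadence_minutes,
                              config$sensor_error)
          ccurve_tabs[[length(ccurve_tabs) + 1]] <- data.frame(
            participant_id = pid, band = band,
            cluster_id = cl$cluster_id, cc)
        }
      }
    }
    psum <- participant_summary(clustersets, use,
                                sensor_error = config$sensor_error)
    psum_tabs[[i]] <- psum
    anova_tabs[[i]] <- psum[, c("participant_id", "band", "anova_f",
                                "anova_df1", "anova_df2", "anova_p",
                                "anova_skip")]
    if (!is.null(inputs$truths)) {
      tr <- inputs$truths[[i]]
      tr_lab <- truth_labels(tr, events)
      truth_tabs[[i]] <- data.frame(participant_id = pid,
                                    event_id = events$event_id,
                                    template_id = tr_lab)
    }
    manifest$participants[[pid]] <- list(
      events_isolated = iso$report$isolated,
      events_excluded = iso$report$excluded,
      imputed_starts = iso$report$imputed_starts,
      clusters = sum(vapply(clustersets, function(cs) length(cs$clusters),
                            integer(1))),
      outliers = sum(vapply(clustersets,
                            function(cs) length(cs$outliers$member_ids),
                            integer(1))))
  }

  write_tab <- function(tabs, file) {
    df <- if (length(tabs)) do.call(rbind, tabs) else data.frame()
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }
  write_tab(ev_tabs, "events.csv")
  write_tab(curve_tabs, "event_curves.csv")
  write_tab(asg_tabs, "assignments.csv")
  write_tab(clsum_tabs, "cluster_summary.csv")
  write_tab(ccurve_tabs, "cluster_curves.csv")
  write_tab(psum_tabs, "participant_summary.csv")
  write_tab(anova_tabs, "anova.csv")
  if (length(truth_tabs)) write_tab(truth_tabs, "truth.csv")

  manifest$status <- "ok"
  manifest$finished <- format_timestamp(Sys.time())
  invisible(manifest)
}
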