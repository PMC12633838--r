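# CV-threshold clustering of PPGR events within one participant x band.
#
# The cohesion statistic is the pooled coefficient of variation: the
# sample standard deviation of all glucose values of a candidate member
# set, divided by the meal-category mean (the mean over every retained
# event of the participant x band, computed once before clustering).

event_pool_stats <- function(events) {
  g <- events$glucose
  t(vapply(g, function(v) {
    v <- v[!is.na(v)]
    c(n = length(v), s = sum(v), q = sum(v^2))
  }, numeric(3)))
}

cv_from_stats <- function(n, s, q, mu) {
  if (n < 2) return(NA_real_)
  v <- (q - s^2 / n) / (n - 1)
  v <- max(v, 0)  # guard tiny negative rounding
  100 * sqrt(v) / mu
}

#' Meal-category context (reference mean)
#'
#' Computes the mean of all glucose values pooled over every retained
#' PPGR event of one participant and meal band (each sample weighted
#' equally).  This mean is the CV denominator for every event and cluster
#' of the category, and is fixed before clustering.
#'
#' @param events A `ppgr_events` data frame from one participant x band.
#' @return An object of class `meal_context`: list with `participant_id`,
#'   `band`, `mu` (mmol/L) and `n_events`.
#' @export
category_mean <- function(events) {
  if (!nrow(events)) stop("category_mean needs at least one event")
  band <- unique(events$band)
  pid <- unique(events$participant_id)
  if (length(band) != 1 || length(pid) != 1) {
    stop("events must come from a single participant and meal band")
  }
  st <- event_pool_stats(events)
  mu <- sum(st[, "s"]) / sum(st[, "n"])
  structure(list(participant_id = pid, band = band, mu = mu,
                 n_events = nrow(events)),
            class = "meal_context")
}

#' Coefficient of variation of one PPGR event
#'
#' 100 x sample standard deviation of the event's raw glucose values,
#' divided by the meal-category mean.
#'
#' @param event One-row `ppgr_events` data frame (or an element subset).
#' @param context A `meal_context` from [category_mean()].
#' @return CV in percent.
#' @export
event_cv <- function(event, context) {
  v <- event$glucose[[1]]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("event_cv needs at least 2 glucose points")
  stopifnot(context$mu > 0)
  100 * stats::sd(v) / context$mu
}

#' Pooled coefficient of variation of a set of PPGR events
#'
#' All member glucose values are pooled into one collection; the CV is
#' 100 x their sample standard deviation over the meal-category mean.
#'
#' @param events `ppgr_events` rows forming the set (>= 1 event).
#' @param context A `meal_context` from [category_mean()].
#' @return CV in percent.
#' @export
pooled_cv <- function(events, context) {
  if (!nrow(events)) stop("pooled_cv needs at least one event")
  stopifnot(context$mu > 0)
  st <- event_pool_stats(events)
  cv_from_stats(sum(st[, "n"]), sum(st[, "s"]), sum(st[, "q"]), context$mu)
}

#' Cluster PPGR events under a CV cohesion constraint
#'
#' Greedy iterative clustering of one participant x band's events:
#'
#' 1. Events are canonically ordered by start time (event id breaks
#'    ties), making the result independent of presentation order.
#' 2. The earliest unassigned event seeds a cluster; remaining
#'    unassigned events are swept in order and added whenever the pooled
#'    CV of the grown cluster stays strictly below `threshold`; sweeps
#'    repeat until a full pass adds nothing.  A grown cluster with at
#'    least two members is committed; a seed that attracts no partner is
#'    set aside as tentative.
#' 3. When no remaining seed can form a multi-member cluster, tentative
#'    events form the outlier group.
#' 4. Multi-membership resolution over the compositions frozen at step
#'    3: every event (outliers included) eligible for several clusters
#'    (pooled CV below threshold on hypothetical inclusion; membership
#'    counts as eligibility) moves to the largest eligible cluster, ties
#'    to the earliest formed.
#' 5. Repair: any cluster whose pooled CV reached the threshold through
#'    moves sheds, one member at a time, the member whose removal lowers
#'    the pooled CV the most (ties: latest added) until it is again below
#'    threshold; shed events and clusters reduced below two members join
#'    the outlier group.
#'
#' Every returned non-outlier cluster has at least two members and a
#' pooled CV strictly below the threshold, and the clusters plus the
#' outlier group partition the input events.
#'
#' @param events A `ppgr_events` data frame from one participant x band.
#' @param threshold CV threshold in percent (default 36).
#' @param context Optional precomputed [category_mean()]; must cover
#'   exactly these events.
#' @return An object of class `cluster_set`: list with `context`,
#'   `clusters` (each: `cluster_id`, `member_ids`, `pooled_cv`,
#'   `is_outlier_group = FALSE`), `outliers` (same shape,
#'   `is_outlier_group = TRUE`, possibly empty) and `threshold`.
#' @export
cluster_category <- function(events, threshold = DEFAULT_CV_THRESHOLD,
                             context = NULL) {
  stopifnot(threshold > 0)
  if (!nrow(events)) {
    return(structure(list(context = NULL, clusters = list(),
                          outliers = list(cluster_id = "outlier",
                                          member_ids = character(),
                                          pooled_cv = NA_real_,
                                          is_outlier_group = TRUE),
                          threshold = threshold),
                     class = "cluster_set"))
  }
  if (is.null(context)) context <- category_mean(events)
  stopifnot(inherits(context, "meal_context"), context$mu > 0)

  ord <- order(as.numeric(events$start), events$event_id)
  events <- events[ord, , drop = FALSE]
  st <- event_pool_stats(events)
  n_ev <- nrow(events)
  mu <- context$mu

  cvset <- function(idx) {
    cv_from_stats(sum(st[idx, "n"]), sum(st[idx, "s"]), sum(st[idx, "q"]), mu)
  }

  # --- greedy growth -------------------------------------------------
  status <- rep("unassigned", n_ev)  # unassigned | tentative | assigned
  clusters <- list()                  # members stored in add order
  repeat {
    seeds <- which(status == "unassigned")
    if (!length(seeds)) break
    s <- seeds[1]
    members <- s
    repeat {
      open <- setdiff(which(status != "assigned"), members)
      added <- FALSE
      for (j in open) {
        if (cvset(c(members, j)) < threshold) {
          members <- c(members, j)
          added <- TRUE
        }
      }
      if (!added) break
    }
    if (length(members) >= 2) {
      status[members] <- "assigned"
      clusters[[length(clusters) + 1]] <- members
    } else {
      status[s] <- "tentative"
    }
  }
  outlier_pool <- which(status == "tentative")

  # --- multi-membership resolution (frozen compositions) -------------
  if (length(clusters)) {
    frozen <- clusters
    sizes <- lengths(frozen)
    home <- rep(0L, n_ev)
    for (k in seq_along(frozen)) home[frozen[[k]]] <- k
    dest <- home
    for (e in seq_len(n_ev)) {
      elig <- vapply(seq_along(frozen), function(k) {
        if (home[e] == k) return(TRUE)
        cvset(c(frozen[[k]], e)) < threshold
      }, logical(1))
      if (!any(elig)) next  # outliers with no eligible cluster stay out
      cand <- which(elig)
      dest[e] <- cand[order(-sizes[cand], cand)][1]
    }
    new_clusters <- vector("list", length(frozen))
    for (k in seq_along(frozen)) {
      stay <- frozen[[k]][dest[frozen[[k]]] == k]       # original add order
      movers <- setdiff(which(dest == k), frozen[[k]])  # canonical order
      new_clusters[[k]] <- c(stay, movers)
    }
    outlier_pool <- which(dest == 0L)

    # --- repair ------------------------------------------------------
    for (k in seq_along(new_clusters)) {
      mem <- new_clusters[[k]]
      while (length(mem) >= 2 && cvset(mem) >= threshold) {
        drop_cv <- vapply(seq_along(mem), function(i) cvset(mem[-i]),
                          numeric(1))
        best <- which(drop_cv == min(drop_cv))
        shed_pos <- best[length(best)]  # tie: latest-added member
        outlier_pool <- c(outlier_pool, mem[shed_pos])
        mem <- mem[-shed_pos]
      }
      if (length(mem) < 2) {
        outlier_pool <- c(outlier_pool, mem)
        mem <- integer()
      }
      new_clusters[[k]] <- mem
    }
    clusters <- new_clusters[lengths(new_clusters) > 0]
  }

  # --- finalize -------------------------------------------------------
  outlier_pool <- sort(unique(outlier_pool))
  cl_out <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    idx <- clusters[[k]]
    cv <- cvset(idx)
    stopifnot(length(idx) >= 2, cv < threshold)  # advertised invariant
    cl_out[[k]] <- list(cluster_id = k,
                        member_ids = events$event_id[sort(idx)],
                        pooled_cv = cv, is_outlier_group = FALSE)
  }
  assigned_n <- sum(lengths(clusters)) + length(outlier_pool)
  stopifnot(assigned_n == n_ev)  # partition invariant

  out_cv <- if (length(outlier_pool)) cvset(outlier_pool) else NA_real_
  structure(list(
    context = context,
    clusters = cl_out,
    outliers = list(cluster_id = "outlier",
                    member_ids = events$event_id[outlier_pool],
                    pooled_cv = out_cv, is_outlier_group = TRUE),
    threshold = threshold), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set%s: %d cluster(s), %d outlier(s), threshold %g%%>\n",
              if (!is.null(x$context)) {
                sprintf(" %s/%s", x$context$participant_id, x$context$band)
              } else "",
              length(x$clusters), length(x$outliers$member_ids),
              x$threshold))
  for (cl in x$clusters) {
    cat(sprintf("  cluster %d: %d events, pooled CV %.2f%%\n",
                cl$cluster_id, length(cl$member_ids), cl$pooled_cv))
  }
  invisible(x)
}

#' Event-to-cluster assignment table
#'
#' @param clusterset A `cluster_set` from [cluster_category()].
#' @return Data frame with columns `event_id` and `cluster` (the cluster
#'   id as character, or `"outlier"`).
#' @export
cluster_assignments <- function(clusterset) {
  stopifnot(inherits(clusterset, "cluster_set"))
  rows <- lapply(clusterset$clusters, function(cl) {
    data.frame(event_id = cl$member_ids,
               cluster = as.character(cl$cluster_id))
  })
  if (length(clusterset$outliers$member_ids)) {
    rows <- c(rows, list(data.frame(
      event_id = clusterset$outliers$member_ids, cluster = "outlier")))
  }
  if (!length(rows)) {
    return(data.frame(event_id = character(), cluster = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$event_id), , drop = FALSE]
}
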