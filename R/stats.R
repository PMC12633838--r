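# Statistical analyses: first-principles one-way ANOVA of carbohydrate
# intake across cluster labels, and the noncentral-t power machinery
# used to solve for a standardized effect size.

anova_skip <- function(reason) {
  structure(list(reason = reason), class = "anova_skip")
}

#' Is an ANOVA result a skip marker?
#' @param x Object returned by [oneway_anova()] or [carb_cluster_test()].
#' @return `TRUE` for a skip marker, else `FALSE`.
#' @export
is_anova_skip <- function(x) inherits(x, "anova_skip")

#' One-way ANOVA from sums of squares
#'
#' Classical between/within decomposition computed directly from the
#' definitions: `SSB = sum n_i (xbar_i - xbar)^2`,
#' `SSW = sum_i sum_j (x_ij - xbar_i)^2`, with
#' `F = (SSB/(k-1)) / (SSW/(N-k))` and the p-value from the F
#' distribution's upper tail.  Fewer than two non-empty groups yields a
#' skip marker (see [is_anova_skip()]) rather than an error, matching the
#' report notation for single-cluster categories.
#'
#' @param groups List of >= 2 numeric vectors (NAs dropped).
#' @return List of class `anova_result` with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `group_sizes` — or an `anova_skip`.
#' @export
oneway_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) {
    return(anova_skip("Not performed due to one cluster formed"))
  }
  sizes <- lengths(groups)
  n_total <- sum(sizes)
  if (n_total <= k) stop("one-way ANOVA needs total N > number of groups")
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- n_total - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(f_stat = f, df_between = df1, df_within = as.integer(df2),
                 p_value = p, group_sizes = unname(sizes)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Carbohydrate ANOVA across a cluster set
#'
#' Groups are the known-carb values of each non-outlier cluster with at
#' least one known-carb event, plus the outlier group when it has any;
#' delegates to [oneway_anova()].  Fewer than two eligible groups
#' propagates a skip marker.
#'
#' @param clusterset A `cluster_set` from [cluster_category()].
#' @param events The category's `ppgr_events`.
#' @return An `anova_result` or `anova_skip`.
#' @export
carb_cluster_test <- function(clusterset, events) {
  stopifnot(inherits(clusterset, "cluster_set"))
  pull_carbs <- function(ids) {
    c0 <- events$carbs_total[match(ids, events$event_id)]
    c0[!is.na(c0)]
  }
  groups <- lapply(clusterset$clusters, function(cl) pull_carbs(cl$member_ids))
  if (length(clusterset$outliers$member_ids)) {
    groups <- c(groups, list(pull_carbs(clusterset$outliers$member_ids)))
  }
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) {
    return(anova_skip(if (!length(groups)) "no known-carb events"
                      else "Not performed due to one cluster formed"))
  }
  oneway_anova(groups)
}

#' Power of the two-sample t test
#'
#' Exact power via the noncentral t distribution with `df = 2n - 2` and
#' noncentrality `d * sqrt(n/2)` for equal per-group size `n`.
#'
#' @param d Cohen's d (standardized mean difference).
#' @param n_per_group Per-group sample size.
#' @param alpha Significance level (default 0.05).
#' @param sides `"two"` (default) or `"one"`.
#' @return Power in (0, 1).
#' @export
t_test_power <- function(d, n_per_group, alpha = 0.05,
                         sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(n_per_group >= 2, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (sides == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Solve the two-sample t-test power equation for Cohen's d
#'
#' Numerically inverts [t_test_power()] in `d` for a given per-group
#' sample size, significance level and target power.  The root is
#' refined until the attained power matches the request to within 1e-8.
#'
#' @param n_per_group Per-group sample size.
#' @param power Target power in (0, 1) (default 0.8).
#' @param alpha Significance level (default 0.05).
#' @param sides `"two"` (default) or `"one"`.
#' @return Cohen's d attaining the requested power.
#' @export
solve_effect_size <- function(n_per_group, power = 0.8, alpha = 0.05,
                              sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(power > 0, power < 1, n_per_group >= 2)
  f <- function(d) t_test_power(d, n_per_group, alpha, sides) - power
  lo <- 1e-9
  hi <- 1
  while (f(hi) < 0 && hi < 1e3) hi <- hi * 2
  if (f(hi) < 0) stop("effect-size root not bracketable")
  d <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(t_test_power(d, n_per_group, alpha, sides) - power) > 1e-8) {
    stop("effect-size solver failed to reach the requested precision")
  }
  d
}
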