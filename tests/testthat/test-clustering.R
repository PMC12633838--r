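# Meal-category CV and the greedy CV-threshold clustering.

test_that("category mean pools every sample with equal weight", {
  ev <- make_events(list(c(5, 7), c(6, 8)))
  expect_equal(category_mean(ev)$mu, 6.5)
  ev1 <- make_events(list(c(4, 6, 8)))
  expect_equal(category_mean(ev1)$mu, 6)
  evc <- make_events(list(c(7, 7), c(7, 7, 7)))
  expect_equal(category_mean(evc)$mu, 7)
})

test_that("event CV is 100 * sample SD over the category mean", {
  ev <- make_events(list(c(4, 6, 8)))
  ctx <- category_mean(ev)
  ctx$mu <- 5  # category mean is an external reference
  expect_equal(event_cv(ev[1, ], ctx), 40)
  evc <- make_events(list(c(6, 6, 6)))
  expect_equal(event_cv(evc[1, ], category_mean(evc)), 0)
})

test_that("CV is invariant to rescaling glucose and mean together", {
  set.seed(7)
  v <- runif(30, 4, 12)
  for (fac in c(0.5, 2, 18.016)) {
    ev1 <- make_events(list(v))
    ev2 <- make_events(list(v * fac))
    expect_equal(event_cv(ev1[1, ], category_mean(ev1)),
                 event_cv(ev2[1, ], category_mean(ev2)),
                 tolerance = 1e-12)
  }
})

test_that("pooled CV matches the plain pooled-sd computation", {
  ev <- make_events(list(c(4, 6, 8), c(4, 6, 8)))
  ctx <- category_mean(ev)
  ctx$mu <- 5
  expect_equal(pooled_cv(ev, ctx), 100 * sd(c(4, 6, 8, 4, 6, 8)) / 5,
               tolerance = 1e-12)
  expect_equal(round(pooled_cv(ev, ctx), 2), 35.78)
  # single-event pooling equals the event CV
  expect_equal(pooled_cv(ev[1, ], ctx), event_cv(ev[1, ], ctx))
  # zero dispersion
  evc <- make_events(list(c(6, 6), c(6, 6)))
  expect_equal(pooled_cv(evc, category_mean(evc)), 0)
})

test_that("identical constant events form a single zero-CV cluster", {
  ev <- make_events(rep(list(rep(6.5, 10)), 5))
  cs <- cluster_category(ev)
  expect_length(cs$clusters, 1)
  expect_equal(length(cs$clusters[[1]]$member_ids), 5)
  expect_equal(cs$clusters[[1]]$pooled_cv, 0)
  expect_length(cs$outliers$member_ids, 0)
})

test_that("a high-variance event is left out as an outlier", {
  vlist <- list(c(5.9, 6.0, 6.1), c(6.0, 6.05, 5.95), c(1, 12, 1, 12))
  ev <- make_events(vlist)
  cs <- cluster_category(ev)
  expect_length(cs$clusters, 1)
  expect_setequal(cs$clusters[[1]]$member_ids, c("E01", "E02"))
  expect_equal(cs$outliers$member_ids, "E03")
  # exhaustive oracle agrees: unique maximal feasible partition
  oracle <- oracle_best_partition(vlist)
  expect_equal(oracle$max_assigned, 2L)
  expect_length(oracle$signatures, 1)
  expect_equal(greedy_signature(cs, ev), oracle$signatures)
})

test_that("clustering is invariant to event presentation order", {
  set.seed(42)
  vlist <- c(lapply(1:4, function(i) rnorm(20, 5, 0.3)),
             lapply(1:4, function(i) rnorm(20, 13, 0.3)),
             list(runif(20, 2, 18)))
  ev <- make_events(vlist)
  ref <- cluster_category(ev)
  for (i in 1:5) {
    perm <- sample(nrow(ev))
    cs <- cluster_category(ev[perm, , drop = FALSE])
    expect_equal(lapply(cs$clusters, `[[`, "member_ids"),
                 lapply(ref$clusters, `[[`, "member_ids"))
    expect_equal(cs$outliers$member_ids, ref$outliers$member_ids)
  }
})

test_that("cluster assignments are scale invariant", {
  set.seed(8)
  vlist <- c(lapply(1:3, function(i) rnorm(12, 4.5, 0.3)),
             lapply(1:3, function(i) rnorm(12, 12, 0.5)))
  ev <- make_events(vlist)
  ref <- cluster_assignments(cluster_category(ev))
  ev2 <- make_events(lapply(vlist, `*`, 3.7))
  expect_equal(cluster_assignments(cluster_category(ev2)), ref)
})

test_that("every output satisfies the CV constraint and partitions events", {
  set.seed(314)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    vlist <- lapply(seq_len(n), function(i) {
      rnorm(sample(24:48, 1), mean = sample(c(4, 7, 13), 1), sd = runif(1, 0.2, 3))
    })
    ev <- make_events(vlist)
    cs <- cluster_category(ev)
    for (cl in cs$clusters) {
      expect_gte(length(cl$member_ids), 2)
      expect_lt(cl$pooled_cv, cs$threshold)
      mem <- ev[match(cl$member_ids, ev$event_id), , drop = FALSE]
      expect_equal(cl$pooled_cv,
                   100 * sd(unlist(mem$glucose)) / cs$context$mu,
                   tolerance = 1e-9)
    }
    all_ids <- c(unlist(lapply(cs$clusters, `[[`, "member_ids")),
                 cs$outliers$member_ids)
    expect_setequal(all_ids, ev$event_id)
    expect_equal(length(all_ids), nrow(ev))
  }
})

test_that("greedy clustering agrees with the exhaustive oracle on micro-instances", {
  set.seed(2024)
  archetypes <- list(
    lo = function() rnorm(8, 4.5, 0.25),
    hi = function() rnorm(8, 13, 0.4),
    wild = function() runif(8, 2, 18))
  n_checked <- 0; n_unique <- 0
  for (inst in 1:40) {
    n <- sample(2:6, 1)
    kinds <- sample(names(archetypes), n, replace = TRUE)
    vlist <- lapply(kinds, function(k) archetypes[[k]]())
    ev <- make_events(vlist)
    cs <- cluster_category(ev)
    oracle <- oracle_best_partition(vlist)
    greedy_assigned <- sum(lengths(lapply(cs$clusters, `[[`, "member_ids")))
    expect_lte(greedy_assigned, oracle$max_assigned)
    if (length(oracle$signatures) == 1) {
      n_unique <- n_unique + 1
      expect_equal(greedy_signature(cs, ev), oracle$signatures)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_unique, 10)  # the grid must actually exercise the match
})

test_that("raising the threshold never increases the outlier count", {
  set.seed(55)
  for (rep in 1:8) {
    vlist <- lapply(1:8, function(i) {
      rnorm(sample(24:48, 1), mean = sample(c(4.5, 8, 13), 1),
            sd = runif(1, 0.2, 2.5))
    })
    ev <- make_events(vlist)
    outs <- vapply(c(25, 36, 50, 80),
                   function(th) length(cluster_category(ev, th)$outliers$member_ids),
                   integer(1))
    expect_true(all(diff(outs) <= 0))
  }
})

test_that("empty input yields an empty cluster set", {
  ev <- make_events(list(c(5, 6)))[0, , drop = FALSE]
  cs <- cluster_category(ev)
  expect_length(cs$clusters, 0)
  expect_length(cs$outliers$member_ids, 0)
})
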