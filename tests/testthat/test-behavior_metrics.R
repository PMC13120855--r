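test_that("ethogram nodes and first-transition edges match hand counts", {
  # A=[0,30), B=[45,60): 0.5 s gap -> edge A->B weight 1; nodes 0.5/0.5
  b <- make_bouts("A", c("lunge", "UWE"), c(0, 45), c(30, 60))
  e <- build_ethogram(b, frame_rate = 30)
  expect_equal(sort(e$nodes$freq), c(0.5, 0.5))
  expect_equal(e$edges$from, "lunge")
  expect_equal(e$edges$to, "UWE")
  expect_equal(e$edges$weight, 1)
  # 1.5 s gap -> no edge
  b2 <- make_bouts("A", c("lunge", "UWE"), c(0, 75), c(30, 90))
  expect_equal(nrow(build_ethogram(b2, 30)$edges), 0)
  # earliest successor only: A then B at 0.2 s and C at 0.8 s
  b3 <- make_bouts("A", c("lunge", "UWE", "circle"),
                   c(0, 36, 54), c(30, 50, 70))
  e3 <- build_ethogram(b3, 30)
  lunge_edges <- e3$edges[e3$edges$from == "lunge", ]
  expect_equal(lunge_edges$to, "UWE")
  # the "all" rule counts both successors
  e3a <- build_ethogram(b3, 30, rule = "all")
  expect_setequal(e3a$edges$to[e3a$edges$from == "lunge"],
                  c("UWE", "circle"))
  # empty table: empty ethogram, no error
  e0 <- build_ethogram(make_bouts(character(), character(), integer(),
                                  integer()), 30)
  expect_equal(nrow(e0$nodes), 0)
})

test_that("ethogram invariants hold and frequencies match a brute-force scan", {
  pr <- behavior_profile(
    c(UWE = 0.06, lunge = 0.05, circle = 0.03),
    dwell = tibble::tibble(action = c("UWE", "lunge", "circle"),
                           shape = 2, mean_s = c(1.5, 0.4, 0.8)))
  for (seed in 1:4) {
    sim <- simulate_dyad(pr, pr, 1200, seed = seed)
    e <- build_ethogram(sim$bouts, 30)
    expect_equal(sum(e$nodes$freq), 1)
    expect_true(all(e$edges$weight >= 0 & e$edges$weight <= 1))
    # per-origin outgoing weights sum to <= 1 under the first-transition rule
    wsum <- tapply(e$edges$weight, e$edges$from, sum)
    expect_true(all(wsum <= 1 + 1e-12))
    # exact match with independent double-loop scan of the same bout list
    bf <- brute_force_transitions(sim$bouts, 30)
    merged <- merge(as.data.frame(e$edges[, c("from", "to", "n")]),
                    as.data.frame(bf), by = c("from", "to"), all = TRUE)
    merged[is.na(merged)] <- 0
    expect_equal(merged$n.x, merged$n.y)
  }
})

test_that("ethogram is invariant under bout-list permutation", {
  pr <- courtship_profile(rate = 0.08)
  sim <- simulate_dyad(pr, pr, 600, seed = 9)
  e1 <- build_ethogram(sim$bouts, 30)
  set.seed(1)
  shuffled <- sim$bouts[sample(nrow(sim$bouts)), ]
  e2 <- build_ethogram(shuffled, 30)
  expect_equal(dplyr::arrange(e1$nodes, action),
               dplyr::arrange(e2$nodes, action))
  expect_equal(dplyr::arrange(e1$edges, from, to),
               dplyr::arrange(e2$edges, from, to))
})

test_that("sliding fraction saturates, plateaus and conserves mass", {
  # full coverage -> identically 1
  b <- make_bouts("A", "UWE", 0, 3600)
  tr <- sliding_fraction(b, "UWE", 10, 30, 3600)
  expect_true(all(tr$fraction == 1))
  # one 30-frame bout, 10 s window: plateau 30/300 = 0.1 where contained
  b2 <- make_bouts("A", "UWE", 1800, 1830)
  tr2 <- sliding_fraction(b2, "UWE", 10, 30, 3600)
  expect_equal(max(tr2$fraction), 0.1, tolerance = 1e-6)
  mid <- tr2$fraction[tr2$frame %in% 1700:1900]
  expect_true(any(abs(mid - 0.1) < 1e-9))
  # conservation: trace mean approximates the overall fraction
  expect_equal(mean(tr2$fraction), 30 / 3600, tolerance = 0.15 * 30 / 3600)
  # a window covering the trial from every center equals fraction_time
  tr3 <- sliding_fraction(b2, "UWE", 2 * 3600 / 30, 30, 3600)
  expect_true(all(abs(tr3$fraction -
                        fraction_time(b2, "UWE", 3600)) < 1e-12))
})

test_that("group traces carry mean and SEM envelopes", {
  traces <- lapply(c(0, 300), function(off) {
    sliding_fraction(make_bouts("A", "UWE", 600 + off, 900 + off),
                     "UWE", 10, 30, 3600)
  })
  g <- group_trace(traces)
  expect_equal(nrow(g), 3600)
  expect_equal(g$mean, (traces[[1]]$fraction + traces[[2]]$fraction) / 2)
  expect_true(all(g$sem >= 0))
})

test_that("fraction_time uses interval union and the effective duration", {
  expect_equal(fraction_time(make_bouts(character(), character(),
                                        integer(), integer()),
                             "UWE", 18000), 0)
  b <- make_bouts("A", "UWE", c(0, 150), c(150, 300))
  expect_equal(fraction_time(b, "UWE", 18000), 300 / 18000)
  # overlapping bouts of the two flies count once in the pooled union
  b2 <- make_bouts(c("A", "B"), "UWE", c(0, 50), c(100, 150))
  expect_equal(fraction_time(b2, "UWE", 300), 0.5)
  pf <- fraction_time(b2, "UWE", 300, per_fly = TRUE)
  expect_equal(sort(pf$fraction), c(100 / 300, 100 / 300))
  expect_error(fraction_time(b, "UWE", 0), "positive")
})

test_that("event rate and latency follow their definitions", {
  # 12 lunges in 20 min -> 0.6/min
  b <- make_bouts("A", "lunge", seq(0, 11) * 3000, seq(0, 11) * 3000 + 10)
  expect_equal(event_rate(b, "lunge", 20 * 60 * 30, 30), 0.6)
  expect_equal(event_rate(b, "UWE", 20 * 60 * 30, 30), 0)
  # truncated trial uses truncated minutes (vs manual crop)
  tr <- dyad_trial(duration = 36000L, copulation_onset = 18000L)
  tc <- truncate_at_copulation(tr, b)
  manual <- b[b$start < 18000, ]
  expect_equal(event_rate(tc$bouts, "lunge", tc$effective_duration, 30),
               event_rate(manual, "lunge", 18000, 30))
  # latency: first UWE at frame 90 -> 3 s
  lb <- make_bouts("A", "UWE", c(90, 300), c(120, 330))
  expect_equal(latency(lb, "UWE", 18000, 30)$time_s, 3)
  cen <- latency(lb, "lunge", 18000, 30)
  expect_true(cen$censored)
  expect_equal(cen$time_s, 600)
})

test_that("cumulative event curves step only at uncensored events", {
  lat <- tibble::tibble(time_s = c(60, 120, 400, 500),
                        censored = c(FALSE, FALSE, TRUE, TRUE))
  cc <- cumulative_event_curve(lat)
  expect_equal(cc$time_s, c(0, 60, 120))
  expect_equal(cc$fraction, c(0, 0.25, 0.5))
  expect_equal(glance(cc)$final_rate, 0.5)
  # all censored -> flat zero
  flat <- cumulative_event_curve(tibble::tibble(time_s = c(600, 600),
                                                censored = TRUE))
  expect_equal(flat$fraction, 0)
  expect_equal(glance(flat)$final_rate, 0)
})

test_that("metrics are invariant under bout-list permutation", {
  pr <- courtship_profile(rate = 0.08)
  b <- simulate_dyad(pr, pr, 600, seed = 2)$bouts
  set.seed(3)
  p <- b[sample(nrow(b)), ]
  expect_equal(fraction_time(p, "UWE", 18000), fraction_time(b, "UWE", 18000))
  expect_equal(event_rate(p, "UWE", 18000, 30), event_rate(b, "UWE", 18000, 30))
  expect_equal(latency(p, "UWE", 18000, 30), latency(b, "UWE", 18000, 30))
})

test_that("ethogram tidiers, DOT export and plots work", {
  b <- make_bouts("A", c("lunge", "UWE"), c(0, 45), c(30, 60))
  e <- build_ethogram(b, 30)
  expect_equal(tidy(e), e$edges)
  expect_equal(glance(e)$n_bouts, 2)
  dot <- ethogram_to_dot(e)
  expect_match(dot, "lunge.*->.*UWE")
  expect_s3_class(autoplot(e), "ggplot")
  expect_s3_class(autoplot(sliding_fraction(b, "UWE", 10, 30, 100)), "ggplot")
})
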