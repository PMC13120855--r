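test_that("ramp protocol lays out onsets deterministically", {
  p <- make_ramp_protocol()
  expect_equal(p$blocks$onset_s, c(120, 210, 300, 390, 480, 570))
  expect_equal(p$blocks$freq_hz, c(1, 2, 5, 10, 20, 40))
  expect_equal(p$baseline_s, 120)
  # zero blocks: baseline-only sham
  p0 <- make_ramp_protocol(frequencies = numeric(0))
  expect_equal(nrow(p0$blocks), 0)
  expect_true(p0$sham)
  expect_error(make_ramp_protocol(frequencies = c(10, 5)), "increasing")
  expect_error(ps_protocol(tibble::tibble(onset_s = c(0, 10),
                                          duration_s = c(20, 10),
                                          freq_hz = c(5, 5))), "overlap")
})

test_that("protocols round-trip through JSON", {
  p <- make_ramp_protocol(intensity = 120)
  path <- withr::local_tempfile(fileext = ".json")
  write_ps_protocol(p, path)
  q <- read_ps_protocol(path)
  expect_equal(q$blocks, p$blocks)
  expect_equal(q$baseline_s, p$baseline_s)
  expect_equal(q$sham, p$sham)
})

test_that("segment masks partition every frame exactly once", {
  prot <- make_ramp_protocol()
  dur <- 630 * 30
  m <- segment_masks(prot, dur, 30)
  expect_equal(sum(m$segments$end - m$segments$start), dur)
  expect_false(any(m$frame_class == ""))
  # classes present: baseline, 6 on, 5 ibi, post
  expect_equal(sum(m$segments$class == "on"), 6)
  expect_equal(sum(m$segments$class == "ibi"), 5)
  expect_equal(sum(m$segments$class == "baseline"), 1)
  expect_equal(sum(m$segments$class == "post"), 1)
  expect_error(segment_masks(prot, 100, 30), "exceeds")
})

test_that("segment aggregation follows the PS+/PS- conventions", {
  prot <- make_ramp_protocol()
  dur <- 630 * 30
  m <- segment_masks(prot, dur, 30)
  # all lunges inside IBIs
  ibi <- m$segments[m$segments$class == "ibi", ]
  b <- make_bouts("A", "lunge", ibi$start + 10, ibi$start + 20)
  a <- aggregate_by_segment(b, m, "lunge")
  expect_equal(a$count[a$segment == "PS+ (OFF)"], 5L)
  expect_equal(a$count[a$segment == "PS-"], 0L)
  # UWE only during blocks
  on <- m$segments[m$segments$class == "on", ]
  b2 <- make_bouts("A", "UWE", on$start, on$end)
  a2 <- aggregate_by_segment(b2, m, "UWE")
  expect_equal(a2$fraction[a2$segment == "PS+ (ON)"], 1)
  expect_equal(a2$fraction[a2$segment == "PS-"], 0)
})

test_that("offset persistence fills IBIs with more lunges than baseline", {
  prot <- make_ramp_protocol()
  pr <- behavior_profile(c(lunge = 0.02),
                         dwell = tibble::tibble(action = "lunge", shape = 2,
                                                mean_s = 0.3),
                         ps_off_amp = 5, ps_off_tau = 30)
  wins <- vapply(1:60, function(s) {
    sim <- simulate_ps_trial(pr, prot, seed = s)
    m <- segment_masks(prot, sim$trial$duration, 30)
    a <- aggregate_by_segment(sim$bouts, m, "lunge")
    off_rate <- a$count[a$segment == "PS+ (OFF)"] /
      a$frames[a$segment == "PS+ (OFF)"]
    base_rate <- a$count[a$segment == "PS-"] / a$frames[a$segment == "PS-"]
    off_rate > base_rate
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("onset-locked curves match a brute-force indicator average", {
  prot <- make_ramp_protocol()
  fr <- 30
  dur <- 630 * fr
  pr <- behavior_profile(c(UWE = 0.05),
                         dwell = tibble::tibble(action = "UWE", shape = 2,
                                                mean_s = 3))
  tabs <- lapply(1:5, function(s) simulate_ps_trial(pr, prot, seed = s)$bouts)
  curve <- ps_locked_fraction(tabs, prot, fr, dur)
  # brute force: same qualification and alignment, written independently
  onsets <- round(prot$blocks$onset_s * fr)
  rel <- round(-1 * fr):round(5 * fr)
  num <- numeric(length(rel)); den <- numeric(length(rel)); nev <- 0
  for (bt in tabs) {
    ab <- bt[bt$action == "UWE", ]
    if (!nrow(ab)) next
    ind <- rep(0L, dur)
    for (i in seq_len(nrow(ab))) ind[(ab$start[i] + 1):ab$end[i]] <- 1L
    for (on in onsets) {
      hit <- FALSE
      for (i in seq_len(nrow(ab))) {
        if (ab$start[i] <= on + 15 && ab$end[i] > on - 15) hit <- TRUE
      }
      if (!hit) next
      nev <- nev + 1
      for (k in seq_along(rel)) {
        f <- on + rel[k]
        if (f >= 0 && f < dur) {
          num[k] <- num[k] + ind[f + 1]; den[k] <- den[k] + 1
        }
      }
    }
  }
  expect_gt(attr(curve, "n_events"), 0)
  expect_equal(attr(curve, "n_events"), nev)
  expect_equal(curve$fraction, num / den)
  expect_s3_class(autoplot(curve), "ggplot")
})

test_that("simulated ON suppression pulls the locked curve down", {
  prot <- make_ramp_protocol()
  # courtship switched off during ON blocks (gain ~ 0)
  pr <- behavior_profile(c(UWE = 0.08),
                         dwell = tibble::tibble(action = "UWE", shape = 2,
                                                mean_s = 4),
                         ps_on_gain = 1e-6)
  tabs <- lapply(1:20, function(s) simulate_ps_trial(pr, prot, seed = s)$bouts)
  curve <- ps_locked_fraction(tabs, prot, 30, 630 * 30)
  pre <- mean(curve$fraction[curve$time_s < 0])
  late <- mean(curve$fraction[curve$time_s > 3])
  expect_gt(pre, late)
  expect_lt(late, 0.5)
})

test_that("no qualifying blocks yields an empty flagged result", {
  prot <- make_ramp_protocol()
  tabs <- list(make_bouts("A", "UWE", 0, 30))  # far from any onset
  curve <- ps_locked_fraction(tabs, prot, 30, 630 * 30)
  expect_equal(attr(curve, "n_events"), 0)
  expect_equal(nrow(curve), 0)
})

test_that("sham persistence baseline uses a strict 2 s threshold", {
  expect_equal(sham_persistence_baseline(c(1, 3, 2.5, 0.8)), 0.5)
  expect_equal(sham_persistence_baseline(c(3, 4, 5)), 1)
  expect_equal(sham_persistence_baseline(c(2.0, 3)), 0.5)  # exactly 2 excluded
  b <- make_bouts("A", "UWE", c(0, 100), c(90, 130))  # 3 s and 1 s at 30 Hz
  expect_equal(sham_persistence_baseline(b, "UWE", frame_rate = 30), 0.5)
  expect_error(sham_persistence_baseline(numeric(0)), "no bouts")
})

test_that("suppression summary counts block-spanning bouts per condition", {
  prot <- make_ramp_protocol()
  fr <- 30
  on_f <- round(prot$blocks$onset_s * fr)
  off_f <- round((prot$blocks$onset_s + prot$blocks$duration_s) * fr)
  # zero suppression: every onset-overlapping bout runs through its block
  persist <- list(make_bouts("A", "UWE", on_f - 30, off_f + 30))
  # full suppression: bouts stop 1 s after onset
  quit <- list(make_bouts("A", "UWE", on_f - 30, on_f + 30))
  base <- sham_persistence_baseline(c(3, 1, 4))
  s <- suppression_summary(list(none = persist, full = quit), prot, fr,
                           baseline = base, action = "UWE")
  expect_equal(s$n_events, c(6L, 6L))
  expect_equal(s$fraction[s$condition == "none"], 1)
  expect_equal(s$fraction[s$condition == "full"], 0)
  expect_equal(unique(s$baseline), base)
  # graded simulated suppression orders conditions with the gain
  mk <- function(gain) {
    pr <- behavior_profile(c(UWE = 0.1),
                           dwell = tibble::tibble(action = "UWE", shape = 2,
                                                  mean_s = 20),
                           ps_on_gain = gain)
    lapply(1:10, function(s) simulate_ps_trial(pr, prot, seed = s)$bouts)
  }
  conds <- list(none = mk(1), strong = mk(1e-6))
  s2 <- suppression_summary(conds, prot, fr, baseline = base,
                            action = "UWE")
  expect_gte(s2$fraction[s2$condition == "none"],
             s2$fraction[s2$condition == "strong"])
  expect_error(suppression_summary(conds, prot, fr, baseline = NULL),
               "baseline")
})

test_that("penetrance and expressivity respond to responder mixtures", {
  prot <- make_ramp_protocol(frequencies = c(5, 10), block_s = 15,
                             baseline_s = 30, ibi_s = 30)
  fr <- 30
  dur <- 150 * fr
  m <- segment_masks(prot, dur, fr)
  on <- m$segments[m$segments$class == "on", ]
  # full responders: threat exactly during ON blocks
  full <- lapply(1:6, function(i) make_bouts("A", "threat", on$start, on$end))
  pe <- penetrance_expressivity(full, fr, dur, masks = m)
  expect_true(all(pe$penetrance$penetrance[m$segments$class == "on"] == 1))
  # no responders
  none <- lapply(1:6, function(i) make_bouts(character(), character(),
                                             integer(), integer()))
  pe0 <- penetrance_expressivity(none, fr, dur, masks = m)
  expect_true(all(pe0$penetrance$penetrance == 0))
  expect_true(all(pe0$expressivity$mean == 0))
  # 50% responder mixture -> ON penetrance 0.5
  mix <- c(full[1:3], none[1:3])
  pem <- penetrance_expressivity(mix, fr, dur, masks = m)
  expect_equal(pem$penetrance$penetrance[m$segments$class == "on"],
               c(0.5, 0.5))
})
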