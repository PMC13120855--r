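test_that("identical seeds give identical output; streams are per fly", {
  pr <- courtship_profile()
  a <- simulate_dyad(pr, pr, 600, seed = 3)
  b <- simulate_dyad(pr, pr, 600, seed = 3)
  expect_identical(a$bouts, b$bouts)
  expect_false(identical(a$bouts,
                         simulate_dyad(pr, pr, 600, seed = 4)$bouts))
})

test_that("generated bout tables satisfy the core invariants", {
  pr <- behavior_profile(
    c(UWE = 0.08, lunge = 0.04, copulation_attempt = 0.01),
    dwell = tibble::tibble(action = c("UWE", "lunge", "copulation_attempt"),
                           shape = 2, mean_s = c(2, 0.4, 1)),
    cop_hazard = 0.05)
  for (seed in 1:8) {
    sim <- simulate_dyad(pr, pr, 900, seed = seed)
    expect_silent(validate_bouts(sim$bouts, sim$trial, action_catalog()))
    if (!is.na(sim$trial$copulation_onset)) {
      tc <- truncate_at_copulation(sim$trial, sim$bouts)
      expect_lte(max(tc$bouts$end), sim$trial$copulation_onset)
    }
  }
})

test_that("zero-rate and degenerate-asymmetry cases are exact", {
  pr <- behavior_profile(c(UWE = 0.05, lunge = 0),
                         dwell = tibble::tibble(action = c("UWE", "lunge"),
                                                shape = 2, mean_s = c(2, 1)))
  sim <- simulate_dyad(pr, pr, 1200, seed = 1)
  expect_false(any(sim$bouts$action == "lunge"))
  # delta = 1: fly B never courts
  pr1 <- courtship_profile(delta = 1)
  sim1 <- simulate_dyad(pr1, pr1, 1200, seed = 2)
  expect_false(any(sim1$bouts$fly_id == "B"))
  expect_gt(sum(sim1$bouts$fly_id == "A"), 0)
})

test_that("bout counts match the renewal-rate oracle", {
  # expected bouts per fly = T / (1/lambda + mu); lambda=0.05, mu=2 -> 54.55
  pr <- courtship_profile(rate = 0.05, mean_s = 2)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_dyad(pr, pr, 1200, seed = s)$bouts) / 2
  }, numeric(1))
  expected <- 1200 / (1 / 0.05 + 2)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)
})

test_that("dwell-time sample means recover the profile mean within 3 SE", {
  pr <- courtship_profile(rate = 0.1, mean_s = 2, shape = 2)
  dur <- unlist(lapply(1:60, function(s) {
    b <- simulate_dyad(pr, pr, 1200, seed = s)$bouts
    (b$end - b$start) / 30
  }))
  se <- sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - 2), 3 * se + 1 / 30)  # frame rounding slack
})

test_that("kernel-driven transition frequencies converge to the kernel", {
  acts <- c("UWE", "BWE", "circle")
  K <- matrix(c(0.6, 0.3, 0.1,
                0.2, 0.5, 0.3,
                0.3, 0.3, 0.4), 3, 3, byrow = TRUE,
              dimnames = list(acts, acts))
  pr <- behavior_profile(setNames(c(0.5, 0, 0), acts),
                         dwell = tibble::tibble(action = acts, shape = 2,
                                                mean_s = 0.5),
                         kernel = K)
  sim <- simulate_dyad(pr, pr, 2600, frame_rate = 30, seed = 5)
  b <- sim$bouts[sim$bouts$fly_id == "A", ]
  b <- b[order(b$start), ]
  expect_gt(nrow(b), 4500)
  from <- b$action[-nrow(b)]
  to <- b$action[-1]
  # only back-to-back chained pairs reflect the kernel draw
  chained <- b$start[-1] == b$end[-nrow(b)]
  tv <- vapply(acts, function(a) {
    emp <- table(factor(to[chained & from == a], levels = acts))
    emp <- emp / sum(emp)
    sum(abs(emp - K[a, ])) / 2
  }, numeric(1))
  expect_true(all(tv < 0.05))
})

test_that("trio preference index matches the analytic ratio", {
  pr <- courtship_profile(rate = 0.04)
  # symmetric targets: index centred on 0
  pis0 <- vapply(1:200, function(s) {
    b <- simulate_trio(pr, c(female = 0.02, male = 0.02), 1200,
                       seed = s)$bouts
    tf <- sum((b$end - b$start)[b$target == "female"])
    tm <- sum((b$end - b$start)[b$target == "male"])
    preference_index(tf / 30, tm / 30)$index
  }, numeric(1))
  expect_lt(abs(mean(pis0, na.rm = TRUE)), 0.05)
  # lambda_M = 0: PI = 1 in every trial with a bout
  b1 <- simulate_trio(pr, c(female = 0.05, male = 0), 1200, seed = 1)$bouts
  expect_true(all(b1$target == "female"))
})

test_that("photostimulation gating concentrates courtship inside ON blocks", {
  prot <- make_ramp_protocol()
  pr <- behavior_profile(c(UWE = 0.01),
                         dwell = tibble::tibble(action = "UWE", shape = 2,
                                                mean_s = 1),
                         ps_on_gain = 10)
  ratios <- vapply(1:60, function(s) {
    sim <- simulate_ps_trial(pr, prot, seed = s)
    m <- segment_masks(prot, sim$trial$duration, 30)
    a <- aggregate_by_segment(sim$bouts, m, "UWE")
    on <- a$fraction[a$segment == "PS+ (ON)"]
    off <- a$fraction[a$segment == "PS+ (OFF)"]
    base <- a$fraction[a$segment == "PS-"]
    on / max(mean(c(off, base)), 1e-6)
  }, numeric(1))
  # two-rate occupancy oracle: ON fraction ~ 10x the light-off fraction
  expect_gt(mean(ratios), 5)
})

test_that("offset-locked aggression decays across the trial in expectation", {
  prot <- make_ramp_protocol()
  pr <- behavior_profile(c(lunge = 0.02),
                         dwell = tibble::tibble(action = "lunge", shape = 2,
                                                mean_s = 0.3),
                         ps_off_amp = 5, ps_off_tau = 30)
  base_rate <- c(); ibi_rate <- c()
  for (s in 1:60) {
    sim <- simulate_ps_trial(pr, prot, seed = s)
    m <- segment_masks(prot, sim$trial$duration, 30)
    a <- aggregate_by_segment(sim$bouts, m, "lunge")
    base_rate <- c(base_rate,
                   a$count[a$segment == "PS-"] / a$frames[a$segment == "PS-"])
    off <- a$segment == "PS+ (OFF)"
    ibi_rate <- c(ibi_rate, a$count[off] / a$frames[off])
  }
  expect_gt(mean(ibi_rate), 2 * mean(base_rate))
})

test_that("null modulation reproduces the protocol-free stream exactly", {
  pr <- courtship_profile(rate = 0.03)
  sham <- ps_protocol(make_ramp_protocol()$blocks, sham = TRUE)
  a <- simulate_ps_trial(pr, sham, duration_s = 600, seed = 11)
  b <- simulate_dyad(pr, pr, 600, seed = 11)
  expect_identical(a$bouts, b$bouts)
})
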