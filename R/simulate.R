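#' Behavior profile for the semi-Markov simulator
#'
#' The simulator generates action bouts per fly as an alternating renewal
#' (semi-Markov) process: from idle, each action `a` initiates after an
#' exponential waiting time at rate `lambda_a` (competing across actions),
#' then dwells for a gamma-distributed duration with shape `k_a` and mean
#' `mu_a`, after which the fly returns to idle — or, when a transition
#' kernel is supplied, chains directly into the next bout drawn from the
#' kernel row (an `"idle"` column, if present, ends the chain).
#'
#' A pair-level dominance asymmetry `delta` scales courtship and
#' aggression initiation between the two flies of a dyad as `(1 + delta)`
#' vs `(1 - delta)`, so the same fly both courts and attacks more.
#' Copulation-attempt bouts carry a per-second copulation hazard; the
#' first copulation event ends the analysis (sets the trial's copulation
#' onset). Photostimulation modulation: during an ON block of pulse
#' frequency f courtship rates are multiplied by the ON gain `g_on(f)`;
#' after each block offset aggression rates are multiplied by
#' `1 + A * exp(-dt / tau)` (offset-locked persistence).
#'
#' @param rates Named numeric vector of initiation rates (events/s) per
#'   action.
#' @param dwell Tibble with columns `action`, `shape`, `mean_s`; actions
#'   missing from it default to shape 2, mean 1 s.
#' @param kernel Optional row-stochastic transition matrix with action row
#'   and column names (columns may include `"idle"`).
#' @param delta Dominance asymmetry in `[0, 1]` applied at the pair level.
#' @param cop_hazard Copulation hazard (per second) during
#'   copulation-attempt bouts.
#' @param ps_on_gain Courtship ON gain: a single number or a function of
#'   pulse frequency (Hz).
#' @param ps_off_amp,ps_off_tau Offset persistence amplitude A (unitless)
#'   and decay constant tau (s, > 0) for aggression.
#' @param catalog [action_catalog()] used to classify actions as courtship
#'   or aggression.
#' @return Object of class `behavior_profile`.
#' @export
behavior_profile <- function(rates, dwell = NULL, kernel = NULL, delta = 0,
                             cop_hazard = 0, ps_on_gain = 1,
                             ps_off_amp = 0, ps_off_tau = 30,
                             catalog = action_catalog()) {
  stopifnot(is.numeric(rates), !is.null(names(rates)))
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and nonnegative")
  }
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  stopifnot(ps_off_tau > 0, cop_hazard >= 0)
  actions <- names(rates)
  dw <- tibble::tibble(action = actions, shape = 2, mean_s = 1)
  if (!is.null(dwell)) {
    dwell <- tibble::as_tibble(dwell)
    stopifnot(all(c("action", "shape", "mean_s") %in% names(dwell)))
    for (i in seq_len(nrow(dwell))) {
      j <- match(dwell$action[i], dw$action)
      if (is.na(j)) stop("dwell for unrated action: ", dwell$action[i])
      dw$shape[j] <- dwell$shape[i]
      dw$mean_s[j] <- dwell$mean_s[i]
    }
  }
  stopifnot(all(dw$shape > 0), all(dw$mean_s > 0))
  if (!is.null(kernel)) {
    kernel <- as.matrix(kernel)
    if (is.null(rownames(kernel)) || is.null(colnames(kernel))) {
      stop("kernel needs action dimnames")
    }
    if (any(abs(rowSums(kernel) - 1) > 1e-8) || any(kernel < 0)) {
      stop("kernel rows must be stochastic")
    }
  }
  structure(list(rates = rates, dwell = dw, kernel = kernel, delta = delta,
                 cop_hazard = cop_hazard, ps_on_gain = ps_on_gain,
                 ps_off_amp = ps_off_amp, ps_off_tau = ps_off_tau,
                 catalog = catalog),
            class = "behavior_profile")
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat(sprintf("<behavior_profile> %d action(s), delta=%.2f, cop_hazard=%.3g/s\n",
              length(x$rates), x$delta, x$cop_hazard))
  print(tibble::tibble(action = names(x$rates), rate_hz = unname(x$rates),
                       shape = x$dwell$shape, mean_s = x$dwell$mean_s))
  invisible(x)
}

# deterministic per-fly substream seed derived from the trial seed
split_seed <- function(seed, index) {
  ((as.numeric(seed) %% 1048576) * 2039 + index * 7919 + 17) %% 2147483647
}

# Core single-fly renewal generator in continuous time.
# rate_fun(t) returns the instantaneous rate vector; rate_max bounds it
# (thinning). When the current total rate equals the bound no thinning
# draw is consumed, so constant-rate simulations share the exact stream
# with null-modulation stimulated ones.
sim_fly_bouts <- function(profile, eff_rates, duration_s,
                          rate_fun = NULL, rate_max = NULL) {
  actions <- names(eff_rates)
  shape <- profile$dwell$shape[match(actions, profile$dwell$action)]
  mu <- profile$dwell$mean_s[match(actions, profile$dwell$action)]
  if (is.null(rate_max)) rate_max <- eff_rates
  lam_max <- sum(rate_max)
  act_v <- character(0); s_v <- numeric(0); e_v <- numeric(0)
  cop_time <- NA_real_
  if (lam_max <= 0) {
    return(list(action = act_v, start_s = s_v, end_s = e_v,
                cop_time = cop_time))
  }
  t <- 0
  repeat {
    t0 <- t + stats::rexp(1, lam_max)
    if (t0 >= duration_s) break
    lam_t <- if (is.null(rate_fun)) eff_rates else rate_fun(t0)
    lam_tot <- sum(lam_t)
    if (lam_tot < lam_max - 1e-12) {
      if (stats::runif(1) >= lam_tot / lam_max) { t <- t0; next }
    }
    if (lam_tot <= 0) { t <- t0; next }
    ai <- sample.int(length(actions), 1, prob = lam_t)
    repeat {                                   # kernel-driven chain
      dw <- stats::rgamma(1, shape = shape[ai], scale = mu[ai] / shape[ai])
      t1 <- t0 + dw
      if (actions[ai] == "copulation_attempt" && profile$cop_hazard > 0) {
        ct <- t0 + stats::rexp(1, profile$cop_hazard)
        if (ct < min(t1, duration_s) && is.na(cop_time)) cop_time <- ct
      }
      act_v <- c(act_v, actions[ai])
      s_v <- c(s_v, t0)
      e_v <- c(e_v, min(t1, duration_s))
      if (t1 >= duration_s) { t <- duration_s; break }
      if (!is.null(profile$kernel) &&
          actions[ai] %in% rownames(profile$kernel)) {
        row <- profile$kernel[actions[ai], ]
        nxt <- sample(colnames(profile$kernel), 1, prob = row)
        if (nxt != "idle" && nxt %in% actions) {
          ai <- match(nxt, actions)
          t0 <- t1
          next
        }
      }
      t <- t1
      break
    }
    if (t >= duration_s) break
  }
  list(action = act_v, start_s = s_v, end_s = e_v, cop_time = cop_time)
}

# continuous-time events -> frame bouts (round half up; drop empty)
events_to_bouts <- function(ev, fly_id, frame_rate, duration_frames) {
  if (!length(ev$action)) {
    return(tibble::tibble(fly_id = character(), action = character(),
                          start = integer(), end = integer()))
  }
  s <- as.integer(floor(ev$start_s * frame_rate + 0.5))
  e <- as.integer(floor(ev$end_s * frame_rate + 0.5))
  e <- pmin(e, as.integer(duration_frames))
  keep <- e > s
  tibble::tibble(fly_id = fly_id, action = ev$action[keep],
                 start = s[keep], end = e[keep])
}

# effective rates for one fly of a dyad given pair-level delta
dominance_scaled_rates <- function(profile, favored) {
  r <- profile$rates
  soc <- c(actions_of_class(profile$catalog, "courtship"),
           actions_of_class(profile$catalog, "aggression"))
  f <- if (favored) 1 + profile$delta else 1 - profile$delta
  sel <- names(r) %in% soc
  r[sel] <- r[sel] * f
  r
}

#' Simulate a dyad trial
#'
#' Generates action bouts for two flies by independent semi-Markov
#' renewal, with fly A favored by the pair-level dominance asymmetry
#' `delta` of `profile_a` (courtship and aggression initiation scaled by
#' `1 + delta` for A and `1 - delta` for B). Copulation-attempt bouts can
#' trigger copulation at the profile's hazard; the earliest copulation
#' across flies sets the trial's copulation onset. Identical seeds give
#' identical output; each fly draws from its own substream, so adding a
#' fly never perturbs another fly's draws.
#'
#' @param profile_a,profile_b [behavior_profile()]s for flies A and B.
#' @param duration_s Trial length (s).
#' @param frame_rate Frames per second (default 30).
#' @param seed Integer seed.
#' @param trial_id Identifier for the generated trial.
#' @return List with `trial` ([trial()]) and `bouts` (tibble).
#' @export
simulate_dyad <- function(profile_a, profile_b = profile_a, duration_s,
                          frame_rate = 30, seed = 1, trial_id = "sim_dyad") {
  dur_f <- as.integer(round(duration_s * frame_rate))
  ra <- dominance_scaled_rates(profile_a, favored = TRUE)
  rb_profile <- profile_b
  rb_profile$delta <- profile_a$delta
  rb <- dominance_scaled_rates(rb_profile, favored = FALSE)
  out <- list()
  cops <- c()
  for (i in 1:2) {
    set.seed(split_seed(seed, i))
    pr <- if (i == 1) profile_a else profile_b
    ev <- sim_fly_bouts(pr, if (i == 1) ra else rb, duration_s)
    out[[i]] <- events_to_bouts(ev, c("A", "B")[i], frame_rate, dur_f)
    if (!is.na(ev$cop_time)) cops <- c(cops, ev$cop_time)
  }
  cop_frame <- if (length(cops)) {
    max(1L, as.integer(floor(min(cops) * frame_rate + 0.5)))
  } else NA_integer_
  if (!is.na(cop_frame) && cop_frame >= dur_f) cop_frame <- NA_integer_
  tr <- trial(trial_id, "dyad", frame_rate, dur_f,
              roster = tibble::tibble(fly_id = c("A", "B"),
                                      sex = c("M", "M")),
              copulation_onset = cop_frame)
  bouts <- dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$fly_id)
  list(trial = tr, bouts = bouts)
}

#' Simulate a trio trial with target-specific courtship
#'
#' One tester fly courts two simultaneously presented targets (a female
#' and a male). Courtship bouts form a single alternating-renewal process:
#' waiting times at the summed rate, target drawn proportionally to the
#' target rates, dwell from the profile's dwell for `action`. By
#' renewal-reward, the expected preference index equals
#' `(lF*muF - lM*muM) / (lF*muF + lM*muM)`.
#'
#' @param profile A [behavior_profile()] supplying the dwell of `action`.
#' @param target_rates Named numeric `c(female = lF, male = lM)`,
#'   initiation rates (events/s) toward each target.
#' @param duration_s Trial length (s).
#' @param frame_rate Frames per second (default 30).
#' @param seed Integer seed.
#' @param action Courtship action label (default `"UWE"`).
#' @param trial_id Identifier.
#' @return List with `trial`, `bouts` (with extra `target` column).
#' @export
simulate_trio <- function(profile, target_rates, duration_s,
                          frame_rate = 30, seed = 1, action = "UWE",
                          trial_id = "sim_trio") {
  stopifnot(all(c("female", "male") %in% names(target_rates)),
            all(target_rates >= 0))
  dur_f <- as.integer(round(duration_s * frame_rate))
  j <- match(action, profile$dwell$action)
  if (is.na(j)) stop("profile has no dwell for action ", action)
  shape <- profile$dwell$shape[j]; mu <- profile$dwell$mean_s[j]
  set.seed(split_seed(seed, 1))
  lam <- sum(target_rates)
  act_v <- character(0); tgt_v <- character(0)
  s_v <- numeric(0); e_v <- numeric(0)
  t <- 0
  while (lam > 0) {
    t0 <- t + stats::rexp(1, lam)
    if (t0 >= duration_s) break
    tgt <- sample(names(target_rates), 1, prob = target_rates)
    dw <- stats::rgamma(1, shape = shape, scale = mu / shape)
    t1 <- min(t0 + dw, duration_s)
    act_v <- c(act_v, action); tgt_v <- c(tgt_v, tgt)
    s_v <- c(s_v, t0); e_v <- c(e_v, t1)
    t <- t0 + dw
  }
  s <- as.integer(floor(s_v * frame_rate + 0.5))
  e <- pmin(as.integer(floor(e_v * frame_rate + 0.5)), dur_f)
  keep <- e > s
  bouts <- tibble::tibble(fly_id = "T", action = act_v[keep],
                          start = s[keep], end = e[keep],
                          target = tgt_v[keep])
  tr <- trial(trial_id, "trio", frame_rate, dur_f,
              roster = tibble::tibble(fly_id = c("T", "F", "M2"),
                                      sex = c("M", "F", "M")))
  list(trial = tr, bouts = bouts)
}

#' Simulate a photostimulation trial
#'
#' Same renewal engine as [simulate_dyad()], but with time-varying
#' initiation rates generated exactly by thinning: during ON blocks
#' courtship rates are multiplied by the profile's ON gain at the block's
#' pulse frequency; after each block offset aggression rates are
#' multiplied by `1 + A * exp(-dt / tau)` where `dt` is the time since the
#' most recent offset. For a sham protocol (or unit gain with `A = 0`) the
#' draw stream is identical to the protocol-free simulation.
#'
#' @param profile A [behavior_profile()].
#' @param protocol A [ps_protocol()].
#' @param duration_s Trial length (s); defaults to the protocol end plus
#'   one inter-block interval worth of tail (60 s).
#' @param pair If `TRUE` (default) two flies are generated, else one.
#' @param frame_rate Frames per second.
#' @param seed Integer seed.
#' @param trial_id Identifier.
#' @return List with `trial` (protocol attached) and `bouts`.
#' @export
simulate_ps_trial <- function(profile, protocol, duration_s = NULL,
                              pair = TRUE, frame_rate = 30, seed = 1,
                              trial_id = "sim_ps") {
  b <- protocol$blocks
  if (is.null(duration_s)) {
    duration_s <- if (nrow(b)) max(b$onset_s + b$duration_s) + 60
                  else protocol$baseline_s + 60
  }
  dur_f <- as.integer(round(duration_s * frame_rate))
  court <- actions_of_class(profile$catalog, "courtship")
  aggr <- actions_of_class(profile$catalog, "aggression")
  gain_at <- function(f) {
    if (is.function(profile$ps_on_gain)) profile$ps_on_gain(f)
    else profile$ps_on_gain
  }
  sham <- isTRUE(protocol$sham) || nrow(b) == 0
  g_max <- if (sham) 1 else max(1, vapply(b$freq_hz, gain_at, numeric(1)))
  a_max <- if (sham) 1 else 1 + profile$ps_off_amp
  offsets <- if (nrow(b)) b$onset_s + b$duration_s else numeric(0)
  n_flies <- if (pair) 2 else 1
  base_list <- lapply(seq_len(n_flies), function(i) {
    dominance_scaled_rates(profile, favored = (i == 1) || !pair)
  })
  make_rate_fun <- function(base) {
    force(base)
    is_court <- names(base) %in% court
    is_aggr <- names(base) %in% aggr
    function(t) {
      r <- base
      if (!sham && nrow(b)) {
        in_block <- which(b$onset_s <= t & t < b$onset_s + b$duration_s)
        if (length(in_block)) {
          r[is_court] <- r[is_court] * gain_at(b$freq_hz[in_block[1]])
        }
        prev_off <- offsets[offsets <= t]
        if (length(prev_off) && profile$ps_off_amp > 0) {
          dt <- t - max(prev_off)
          r[is_aggr] <- r[is_aggr] *
            (1 + profile$ps_off_amp * exp(-dt / profile$ps_off_tau))
        }
      }
      r
    }
  }
  out <- list(); cops <- c()
  for (i in seq_len(n_flies)) {
    base <- base_list[[i]]
    rmax <- base
    rmax[names(base) %in% court] <- rmax[names(base) %in% court] * g_max
    rmax[names(base) %in% aggr] <- rmax[names(base) %in% aggr] * a_max
    set.seed(split_seed(seed, i))
    ev <- sim_fly_bouts(profile, base, duration_s,
                        rate_fun = if (sham) NULL else make_rate_fun(base),
                        rate_max = rmax)
    out[[i]] <- events_to_bouts(ev, c("A", "B")[i], frame_rate, dur_f)
    if (!is.na(ev$cop_time)) cops <- c(cops, ev$cop_time)
  }
  cop_frame <- if (length(cops)) {
    max(1L, as.integer(floor(min(cops) * frame_rate + 0.5)))
  } else NA_integer_
  if (!is.na(cop_frame) && cop_frame >= dur_f) cop_frame <- NA_integer_
  roster <- if (pair) {
    tibble::tibble(fly_id = c("A", "B"), sex = c("M", "M"))
  } else tibble::tibble(fly_id = "A", sex = "M")
  tr <- trial(trial_id, if (pair) "dyad" else "solitary", frame_rate, dur_f,
              roster = roster, copulation_onset = cop_frame,
              protocol = protocol)
  bouts <- dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$fly_id)
  list(trial = tr, bouts = bouts)
}
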