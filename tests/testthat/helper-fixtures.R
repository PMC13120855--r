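# Shared fixtures: small hand-built bout tables and a default profile.

make_bouts <- function(fly_id, action, start, end) {
  tibble::tibble(fly_id = fly_id, action = action,
                 start = as.integer(start), end = as.integer(end))
}

dyad_trial <- function(duration = 18000L, frame_rate = 30,
                       copulation_onset = NA_integer_) {
  trial("t1", "dyad", frame_rate, duration,
        roster = tibble::tibble(fly_id = c("A", "B"), sex = c("M", "M")),
        copulation_onset = copulation_onset)
}

courtship_profile <- function(rate = 0.05, mean_s = 2, shape = 2, ...) {
  behavior_profile(c(UWE = rate),
                   dwell = tibble::tibble(action = "UWE", shape = shape,
                                          mean_s = mean_s), ...)
}

# independent brute-force first-transition scan used against build_ethogram
brute_force_transitions <- function(bouts, frame_rate, window_s = 1) {
  wf <- round(window_s * frame_rate)
  out <- list()
  for (f in unique(bouts$fly_id)) {
    fb <- bouts[bouts$fly_id == f, ]
    fb <- fb[order(fb$start, fb$end), ]
    n <- nrow(fb)
    if (n < 2) next
    for (i in seq_len(n)) {
      best <- NA_integer_
      for (j in seq_len(n)) {
        if (j == i) next
        if (fb$start[j] >= fb$end[i] && fb$start[j] <= fb$end[i] + wf) {
          if (is.na(best) || fb$start[j] < fb$start[best]) best <- j
        }
      }
      if (!is.na(best)) {
        out[[length(out) + 1]] <- c(from = fb$action[i],
                                    to = fb$action[best])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(from = character(), to = character(),
                          n = integer()))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  dplyr::count(df, from, to, name = "n") |> tibble::as_tibble()
}

# independent O(n^2) transitive-closure clustering for train segmentation
brute_force_trains <- function(events, thresholds = c(pulse = 0.2,
                                                      clack = 0.4)) {
  events <- events[order(events$time), ]
  lab <- integer(nrow(events))
  nxt <- 0L
  for (ty in unique(events$type)) {
    idx <- which(events$type == ty)
    thr <- thresholds[[ty]]
    comp <- seq_along(idx)
    repeat {
      changed <- FALSE
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a != b && abs(events$time[idx[a]] - events$time[idx[b]]) < thr &&
            comp[a] != comp[b]) {
          comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    lab[idx] <- nxt + match(comp, unique(comp))
    nxt <- nxt + length(unique(comp))
  }
  lab
}

# independent step-up BH implementation
brute_force_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(vapply(js, function(j) {
      m * p[j] / sum(p <= p[j])
    }, numeric(1))))
  }, numeric(1))
}
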