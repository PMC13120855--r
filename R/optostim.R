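#' Photostimulation protocol
#'
#' An ordered set of non-overlapping light-ON blocks, each with an onset
#' (seconds from trial start), duration, LED pulse frequency, pulse width
#' and intensity label, preceded by a light-off baseline. Pulse width and
#' duty cycle are carried through serialization only; analyses treat ON
#' blocks as intervals.
#'
#' @param blocks Tibble/data.frame with columns `onset_s`, `duration_s`,
#'   `freq_hz` and optionally `pulse_ms` (default 10) and `intensity`
#'   (uW/mm^2 label).
#' @param baseline_s Light-off period before the first block (seconds).
#' @param sham Logical; a sham protocol has the identical block layout but
#'   delivers no effective light.
#' @return Object of class `ps_protocol`.
#' @export
ps_protocol <- function(blocks, baseline_s = NULL, sham = FALSE) {
  blocks <- tibble::as_tibble(blocks)
  if (nrow(blocks)) {
    stopifnot(all(c("onset_s", "duration_s", "freq_hz") %in% names(blocks)))
    if (!"pulse_ms" %in% names(blocks)) blocks$pulse_ms <- 10
    if (!"intensity" %in% names(blocks)) blocks$intensity <- NA_real_
    if (is.unsorted(blocks$onset_s, strictly = TRUE)) {
      stop("block onsets must be strictly increasing")
    }
    offs <- blocks$onset_s + blocks$duration_s
    if (any(utils::head(offs, -1) > utils::tail(blocks$onset_s, -1))) {
      stop("photostimulation blocks overlap")
    }
    if (any(blocks$freq_hz < 1 | blocks$freq_hz > 40)) {
      stop("pulse frequency outside [1, 40] Hz")
    }
    if (is.null(baseline_s)) baseline_s <- blocks$onset_s[1]
  } else if (is.null(baseline_s)) {
    baseline_s <- 0
  }
  structure(list(blocks = blocks, baseline_s = baseline_s, sham = sham),
            class = "ps_protocol")
}

#' @export
print.ps_protocol <- function(x, ...) {
  cat(sprintf("<ps_protocol> %d block(s), %g s baseline%s\n",
              nrow(x$blocks), x$baseline_s, if (x$sham) ", sham" else ""))
  if (nrow(x$blocks)) print(x$blocks)
  invisible(x)
}

#' Canonical frequency-ramp protocol
#'
#' The standard assay layout: a 2 min baseline followed by six 30 s ON
#' blocks at fixed intensity and monotonically increasing pulse frequency,
#' separated by 1 min inter-block intervals. With the defaults the block
#' onsets fall at 120, 210, 300, 390, 480 and 570 s.
#'
#' @param frequencies Ascending pulse frequencies (Hz), one per block.
#'   Default ladder `c(1, 2, 5, 10, 20, 40)`.
#' @param block_s ON-block duration (s).
#' @param baseline_s Pre-stimulus baseline (s).
#' @param ibi_s Inter-block interval (s).
#' @param intensity Intensity label (uW/mm^2), common to all blocks.
#' @param sham Logical sham flag.
#' @return A [ps_protocol()].
#' @examples
#' make_ramp_protocol()$blocks$onset_s  # 120 210 300 390 480 570
#' @export
make_ramp_protocol <- function(frequencies = c(1, 2, 5, 10, 20, 40),
                               block_s = 30, baseline_s = 120, ibi_s = 60,
                               intensity = NA_real_, sham = FALSE) {
  if (length(frequencies) == 0) {
    return(ps_protocol(tibble::tibble(onset_s = numeric(),
                                      duration_s = numeric(),
                                      freq_hz = numeric()),
                       baseline_s = baseline_s, sham = TRUE))
  }
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("ramp protocol requires strictly increasing frequencies")
  }
  k <- seq_along(frequencies) - 1
  blocks <- tibble::tibble(
    onset_s = baseline_s + k * (block_s + ibi_s),
    duration_s = block_s, freq_hz = as.numeric(frequencies),
    pulse_ms = 10, intensity = intensity)
  ps_protocol(blocks, baseline_s = baseline_s, sham = sham)
}

ps_protocol_to_list <- function(p) {
  list(blocks = p$blocks, baseline_s = p$baseline_s, sham = p$sham)
}

ps_protocol_from_list <- function(x) {
  ps_protocol(tibble::as_tibble(as.data.frame(x$blocks)),
              baseline_s = x$baseline_s, sham = isTRUE(x$sham))
}

#' Read / write a photostimulation protocol as JSON
#'
#' @param path JSON file path.
#' @return `read_ps_protocol()` returns a [ps_protocol()];
#'   `write_ps_protocol()` returns the path invisibly.
#' @export
read_ps_protocol <- function(path) {
  ps_protocol_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_ps_protocol
#' @param protocol A [ps_protocol()].
#' @export
write_ps_protocol <- function(protocol, path) {
  jsonlite::write_json(ps_protocol_to_list(protocol), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Partition a trial into photostimulation segments
#'
#' Labels every frame of a trial as baseline (the light-off period before
#' the first block, the "PS-" reference), one of the ON blocks, one of the
#' inter-block intervals (IBIs), or the period following the final block.
#' The segments partition the trial exactly.
#'
#' @param protocol A [ps_protocol()].
#' @param trial_duration Trial length in frames.
#' @param frame_rate Frames per second.
#' @return Object of class `ps_segments`: a list with `segments` (tibble
#'   `segment`, `class` in baseline/on/ibi/post, `start`, `end` frames,
#'   half-open) and `frame_class` (per-frame factor of segment labels).
#' @export
segment_masks <- function(protocol, trial_duration, frame_rate) {
  b <- protocol$blocks
  to_f <- function(s) as.integer(round(s * frame_rate))
  segs <- list()
  if (nrow(b) == 0) {
    segs[[1]] <- tibble::tibble(segment = "baseline", class = "baseline",
                                start = 0L, end = as.integer(trial_duration))
  } else {
    on_start <- to_f(b$onset_s)
    on_end <- to_f(b$onset_s + b$duration_s)
    if (max(on_end) > trial_duration) stop("protocol exceeds trial duration")
    segs[[1]] <- tibble::tibble(segment = "baseline", class = "baseline",
                                start = 0L, end = on_start[1])
    for (i in seq_len(nrow(b))) {
      segs[[length(segs) + 1]] <- tibble::tibble(
        segment = sprintf("on_%d", i), class = "on",
        start = on_start[i], end = on_end[i])
      nxt <- if (i < nrow(b)) on_start[i + 1] else as.integer(trial_duration)
      lab <- if (i < nrow(b)) sprintf("ibi_%d", i) else "post"
      cls <- if (i < nrow(b)) "ibi" else "post"
      if (nxt > on_end[i]) {
        segs[[length(segs) + 1]] <- tibble::tibble(
          segment = lab, class = cls, start = on_end[i], end = nxt)
      }
    }
  }
  segments <- dplyr::bind_rows(segs)
  frame_class <- character(trial_duration)
  for (i in seq_len(nrow(segments))) {
    frame_class[(segments$start[i] + 1):segments$end[i]] <-
      segments$segment[i]
  }
  structure(list(segments = segments, frame_class = frame_class,
                 frame_rate = frame_rate,
                 trial_duration = as.integer(trial_duration)),
            class = "ps_segments")
}

#' Aggregate a behavior by photostimulation segment
#'
#' Computes, per segment, the bout-onset count and the fraction of segment
#' time spent in the action, then pools them into the conventional summary
#' rows: `PS-` (the pre-stimulus baseline), `PS+ (ON)` (all ON blocks
#' cumulatively; the convention for courtship), and `PS+ (OFF)` (all IBIs
#' plus the period following the final block; the convention for
#' aggression, which is expressed mostly during light-off periods).
#'
#' @param bouts Bout tibble.
#' @param masks A [segment_masks()] result.
#' @param action Action label to aggregate.
#' @return Tibble with `segment`, `class`, `frames`, `count`
#'   (bout onsets in segment), `time_frames` (action frames in segment) and
#'   `fraction` (time_frames/frames); pooled rows have class `"pooled"`.
#' @export
aggregate_by_segment <- function(bouts, masks, action) {
  segs <- masks$segments
  ab <- bouts[bouts$action == action, , drop = FALSE]
  ind <- frame_indicator(ab, masks$trial_duration)
  res <- segs
  res$frames <- segs$end - segs$start
  res$count <- vapply(seq_len(nrow(segs)), function(i) {
    sum(ab$start >= segs$start[i] & ab$start < segs$end[i])
  }, integer(1))
  res$time_frames <- vapply(seq_len(nrow(segs)), function(i) {
    sum(ind[(segs$start[i] + 1):segs$end[i]])
  }, integer(1))
  res$fraction <- res$time_frames / pmax(res$frames, 1)
  pool <- function(label, classes) {
    sel <- res$class %in% classes
    tibble::tibble(segment = label, class = "pooled",
                   frames = sum(res$frames[sel]),
                   count = sum(res$count[sel]),
                   time_frames = sum(res$time_frames[sel]),
                   fraction = sum(res$time_frames[sel]) /
                     max(sum(res$frames[sel]), 1))
  }
  dplyr::bind_rows(res,
                   pool("PS-", "baseline"),
                   pool("PS+ (ON)", "on"),
                   pool("PS+ (OFF)", c("ibi", "post")))
}

# 0/1 per-frame indicator (length duration) of the union of bout intervals
frame_indicator <- function(bouts, duration) {
  ind <- integer(duration)
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      s <- max(bouts$start[i], 0L)
      e <- min(bouts$end[i], duration)
      if (e > s) ind[(s + 1):e] <- 1L
    }
  }
  ind
}

#' Stimulus-locked behavior fraction around block onsets
#'
#' For each trial and ON block, the (trial, block) event qualifies when an
#' action bout overlaps the interval `[onset - onset_filter_s,
#' onset + onset_filter_s]` (the fly showed spontaneous behavior within
#' 0.5 s of PS onset, by default). Qualifying events are aligned to block
#' onset and the binary per-frame action indicator is averaged across
#' events over a surrounding window, producing a fraction-of-flies-courting
#' curve suitable for comparison against sham trials.
#'
#' @param bout_tables List of bout tibbles, one per trial (all same layout).
#' @param protocol A [ps_protocol()] (block onsets taken from it).
#' @param frame_rate Frames per second.
#' @param duration Trial length in frames.
#' @param action Action label (default `"UWE"`).
#' @param window_s Length-2 numeric, window around onset in seconds
#'   (default `c(-1, 5)`, a 6 s window surrounding the block onset).
#' @param onset_filter_s Half-width of the qualifying overlap window (s).
#' @return Object of class `ps_locked_curve`: tibble columns `time_s`
#'   (relative to onset), `fraction`, plus attribute `n_events`. If no
#'   (trial, block) qualifies, a zero-row curve with `n_events = 0`.
#' @export
ps_locked_fraction <- function(bout_tables, protocol, frame_rate, duration,
                               action = "UWE", window_s = c(-1, 5),
                               onset_filter_s = 0.5) {
  stopifnot(length(window_s) == 2, window_s[2] > window_s[1])
  onsets_f <- round(protocol$blocks$onset_s * frame_rate)
  filt_f <- round(onset_filter_s * frame_rate)
  w0 <- round(window_s[1] * frame_rate)
  w1 <- round(window_s[2] * frame_rate)
  rel <- w0:w1
  acc <- numeric(length(rel))
  nav <- integer(length(rel))
  n_events <- 0L
  for (bt in bout_tables) {
    ab <- bt[bt$action == action, , drop = FALSE]
    if (!nrow(ab)) next
    ind <- frame_indicator(ab, duration)
    for (on_f in onsets_f) {
      qualifies <- any(ab$start <= on_f + filt_f & ab$end > on_f - filt_f)
      if (!qualifies) next
      n_events <- n_events + 1L
      fr <- on_f + rel
      ok <- fr >= 0 & fr < duration
      acc[ok] <- acc[ok] + ind[fr[ok] + 1]
      nav[ok] <- nav[ok] + 1L
    }
  }
  curve <- if (n_events == 0) {
    tibble::tibble(time_s = numeric(), fraction = numeric())
  } else {
    tibble::tibble(time_s = rel / frame_rate,
                   fraction = ifelse(nav > 0, acc / nav, NA_real_))
  }
  structure(curve, n_events = n_events, action = action,
            class = c("ps_locked_curve", class(curve)))
}

#' Sham persistence baseline
#'
#' Fraction of spontaneous action bouts in sham trials lasting strictly
#' more than `min_s` seconds (default 2 s), the baseline against which
#' stimulus-locked suppression is judged.
#'
#' @param x Either a bout tibble (or list of them) with `start`/`end`
#'   frames — then `frame_rate` is required — or a numeric vector of bout
#'   durations in seconds.
#' @param action Action label (ignored for a duration vector).
#' @param frame_rate Frames per second (bout-table input only).
#' @param min_s Strict duration threshold in seconds.
#' @return Single numeric fraction.
#' @export
sham_persistence_baseline <- function(x, action = "UWE", frame_rate = NULL,
                                      min_s = 2) {
  if (is.numeric(x)) {
    dur <- x
  } else {
    if (is.data.frame(x)) x <- list(x)
    stopifnot(!is.null(frame_rate))
    dur <- unlist(lapply(x, function(bt) {
      ab <- bt[bt$action == action, , drop = FALSE]
      (ab$end - ab$start) / frame_rate
    }))
  }
  if (!length(dur)) stop("no bouts to compute a persistence baseline from")
  mean(dur > min_s)
}

#' Summary of stimulus-locked suppression across conditions
#'
#' For each condition (e.g. an intensity x target-sex cell), takes the
#' qualifying (trial, block) events as in [ps_locked_fraction()] and
#' reports the fraction whose onset-overlapping bout persisted through the
#' entire ON block, alongside the sham persistence baseline. Any
#' monotonicity in intensity is reported, never assumed.
#'
#' @param conditions Named list; each element a list of bout tibbles
#'   (trials) for one condition.
#' @param protocol A [ps_protocol()].
#' @param frame_rate Frames per second.
#' @param baseline Sham baseline fraction from
#'   [sham_persistence_baseline()].
#' @param action Action label.
#' @param onset_filter_s Qualifying overlap half-width (s).
#' @return Tibble `condition`, `n_events`, `persisting`, `fraction`,
#'   `baseline`.
#' @export
suppression_summary <- function(conditions, protocol, frame_rate, baseline,
                                action = "UWE", onset_filter_s = 0.5) {
  if (is.null(baseline)) stop("a sham baseline is required")
  onsets_f <- round(protocol$blocks$onset_s * frame_rate)
  offs_f <- round((protocol$blocks$onset_s + protocol$blocks$duration_s) *
                    frame_rate)
  filt_f <- round(onset_filter_s * frame_rate)
  purrr::imap_dfr(conditions, function(trials, cond) {
    n_ev <- 0L; n_pers <- 0L
    for (bt in trials) {
      ab <- bt[bt$action == action, , drop = FALSE]
      if (!nrow(ab)) next
      for (i in seq_along(onsets_f)) {
        sel <- ab$start <= onsets_f[i] + filt_f & ab$end > onsets_f[i] - filt_f
        if (!any(sel)) next
        n_ev <- n_ev + 1L
        if (any(ab$end[sel] >= offs_f[i])) n_pers <- n_pers + 1L
      }
    }
    tibble::tibble(condition = cond, n_events = n_ev, persisting = n_pers,
                   fraction = if (n_ev) n_pers / n_ev else NA_real_,
                   baseline = baseline)
  })
}

#' Penetrance and expressivity of a stimulus-locked behavior
#'
#' Penetrance is the fraction of flies showing the action at least once in
#' a time bin; expressivity is the group mean (with SEM envelope) of the
#' per-fly sliding-window fraction of frames in the action.
#'
#' @param bout_tables List of per-fly bout tibbles (aligned trials).
#' @param frame_rate Frames per second.
#' @param duration Trial length in frames.
#' @param action Action label (default `"threat"`).
#' @param window_s Sliding window for expressivity (s), default 5.
#' @param bin_s Bin width for penetrance (s); alternatively pass `masks`.
#' @param masks Optional [segment_masks()]; if given, its segments are used
#'   as the penetrance bins instead of uniform `bin_s` bins.
#' @return List with `penetrance` (tibble `bin`, `start_s`, `end_s`,
#'   `penetrance`) and `expressivity` (tibble `time_s`, `mean`, `sem`).
#' @export
penetrance_expressivity <- function(bout_tables, frame_rate, duration,
                                    action = "threat", window_s = 5,
                                    bin_s = 5, masks = NULL) {
  if (!is.null(masks)) {
    bins <- masks$segments[, c("segment", "start", "end")]
  } else {
    bw <- round(bin_s * frame_rate)
    starts <- seq(0L, duration - 1L, by = bw)
    bins <- tibble::tibble(segment = sprintf("bin_%d", seq_along(starts)),
                           start = starts,
                           end = pmin(starts + bw, duration))
  }
  inds <- lapply(bout_tables, function(bt) {
    frame_indicator(bt[bt$action == action, , drop = FALSE], duration)
  })
  pen <- vapply(seq_len(nrow(bins)), function(i) {
    mean(vapply(inds, function(ind) {
      any(ind[(bins$start[i] + 1):bins$end[i]] > 0)
    }, logical(1)))
  }, numeric(1))
  penetrance <- tibble::tibble(bin = bins$segment,
                               start_s = bins$start / frame_rate,
                               end_s = bins$end / frame_rate,
                               penetrance = pen)
  traces <- vapply(bout_tables, function(bt) {
    sliding_fraction(bt, action, window_s, frame_rate, duration)$fraction
  }, numeric(duration))
  m <- rowMeans(traces)
  sem <- apply(traces, 1, stats::sd) / sqrt(ncol(traces))
  expressivity <- tibble::tibble(time_s = (seq_len(duration) - 1) / frame_rate,
                                 mean = m, sem = sem)
  list(penetrance = penetrance, expressivity = expressivity)
}
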