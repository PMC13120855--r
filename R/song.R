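#' Song synthesis specification
#'
#' Parameters for generating synthetic courtship-song waveforms with exact
#' ground truth: each event is a short carrier burst under a Gaussian
#' envelope whose noise-free peak sits exactly on a sample; events are
#' organized into trains with within-train gaps below the segmentation
#' threshold of their type and between-train gaps above it.
#'
#' @param sample_rate Samples per second (default 10000; must be at least
#'   twice the fastest carrier).
#' @param pulse_carrier_hz,clack_carrier_hz Carrier frequencies (Hz).
#' @param pulse_sigma_ms,clack_sigma_ms Gaussian envelope widths (ms).
#' @param amp_mean,amp_sd Event peak amplitude distribution (truncated at
#'   0.1 from below).
#' @param pulse_gap_s,clack_gap_s Length-2 ranges (s) for within-train
#'   gaps; defaults keep pulse gaps under 0.2 s and clack gaps under
#'   0.4 s.
#' @param train_gap_s Length-2 range (s) for between-train gaps.
#' @param train_size Length-2 integer range of events per train.
#' @param noise_sd Additive Gaussian background noise SD.
#' @return Object of class `song_synth_spec`.
#' @export
song_synth_spec <- function(sample_rate = 10000, pulse_carrier_hz = 250,
                            clack_carrier_hz = 170, pulse_sigma_ms = 3,
                            clack_sigma_ms = 8, amp_mean = 1, amp_sd = 0.2,
                            pulse_gap_s = c(0.08, 0.15),
                            clack_gap_s = c(0.22, 0.35),
                            train_gap_s = c(0.8, 1.6),
                            train_size = c(3, 8), noise_sd = 0.02) {
  stopifnot(sample_rate >= 2 * max(pulse_carrier_hz, clack_carrier_hz),
            all(c(pulse_gap_s, clack_gap_s, train_gap_s) > 0),
            noise_sd >= 0)
  structure(list(sample_rate = sample_rate,
                 carrier = c(pulse = pulse_carrier_hz,
                             clack = clack_carrier_hz),
                 sigma_ms = c(pulse = pulse_sigma_ms,
                              clack = clack_sigma_ms),
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 gap_s = list(pulse = pulse_gap_s, clack = clack_gap_s),
                 train_gap_s = train_gap_s, train_size = train_size,
                 noise_sd = noise_sd),
            class = "song_synth_spec")
}

#' Synthesize a courtship-song waveform with ground truth
#'
#' Lays out pulse and clack trains on a common timeline (types
#' interleaved train-by-train), renders each event as an
#' amplitude-modulated carrier burst whose noise-free peak lies exactly at
#' the event time, and adds Gaussian background noise. Returns the exact
#' event times, amplitudes and train memberships.
#'
#' @param spec A [song_synth_spec()].
#' @param n_trains Named integer vector `c(pulse = , clack = )`.
#' @param seed Integer seed.
#' @return List with `waveform` (numeric vector), `sample_rate`, and
#'   `events` (tibble `type`, `time`, `amplitude`, `train`).
#' @export
synthesize_song <- function(spec, n_trains = c(pulse = 3, clack = 2),
                            seed = 1) {
  set.seed(seed)
  types <- rep(c("pulse", "clack"),
               c(n_trains[["pulse"]], n_trains[["clack"]]))
  if (length(types) > 1) types <- sample(types)
  sr <- spec$sample_rate
  t_cursor <- 0.1
  rows <- list()
  train_id <- c(pulse = 0L, clack = 0L)
  for (ty in types) {
    train_id[ty] <- train_id[ty] + 1L
    k <- sample(spec$train_size[1]:spec$train_size[2], 1)
    gaps <- stats::runif(k - 1, spec$gap_s[[ty]][1], spec$gap_s[[ty]][2])
    times <- t_cursor + c(0, cumsum(gaps))
    times <- round(times * sr) / sr          # snap peaks onto samples
    amps <- pmax(0.1, stats::rnorm(k, spec$amp_mean, spec$amp_sd))
    rows[[length(rows) + 1]] <- tibble::tibble(
      type = ty, time = times, amplitude = amps,
      train = sprintf("%s_%d", ty, train_id[ty]))
    t_cursor <- max(times) +
      stats::runif(1, spec$train_gap_s[1], spec$train_gap_s[2])
  }
  events <- if (length(rows)) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$time)
  } else {
    tibble::tibble(type = character(), time = numeric(),
                   amplitude = numeric(), train = character())
  }
  total_s <- if (nrow(events)) max(events$time) + 0.2 else 1
  n <- ceiling(total_s * sr)
  wave <- numeric(n)
  tt <- (seq_len(n) - 1) / sr
  for (i in seq_len(nrow(events))) {
    t0 <- events$time[i]
    sig <- spec$sigma_ms[[events$type[i]]] / 1000
    f <- spec$carrier[[events$type[i]]]
    win <- which(abs(tt - t0) < 5 * sig)
    wave[win] <- wave[win] + events$amplitude[i] *
      cos(2 * pi * f * (tt[win] - t0)) *
      exp(-(tt[win] - t0)^2 / (2 * sig^2))
  }
  if (spec$noise_sd > 0) wave <- wave + stats::rnorm(n, 0, spec$noise_sd)
  list(waveform = wave, sample_rate = sr, events = events)
}

#' Refine annotated event peaks against the waveform
#'
#' Coarse manual annotations mark events only approximately; the exact
#' amplitude and position of each event's peak is the maximum signal
#' intensity within a 20 ms window centered on the annotation point
#' (windows truncate at waveform edges). Intensity is the absolute
#' amplitude by default (song pulses are biphasic); two equal maxima
#' resolve to the earlier sample, and a perfectly flat window returns the
#' annotation point itself.
#'
#' @param waveform Numeric sampled signal.
#' @param sample_rate Samples per second.
#' @param annotation_time Annotation time(s) in seconds (vectorized).
#' @param window_ms Window length (ms), default 20.
#' @param mode `"abs"` (default) or `"signed"` maximum.
#' @return Tibble with `annotation`, `time`, `amplitude` (intensity at the
#'   refined peak, absolute under `"abs"`).
#' @export
refine_peak <- function(waveform, sample_rate, annotation_time,
                        window_ms = 20, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  n <- length(waveform)
  half <- round(window_ms / 1000 * sample_rate / 2)
  purrr::map_dfr(annotation_time, function(at) {
    ci <- round(at * sample_rate) + 1
    if (ci < 1 || ci > n) stop("annotation outside waveform: ", at)
    lo <- max(1, ci - half); hi <- min(n, ci + half)
    seg <- waveform[lo:hi]
    val <- if (mode == "abs") abs(seg) else seg
    if (max(val) - min(val) == 0) {           # flat: keep the center
      idx <- ci
    } else {
      idx <- lo + which.max(val) - 1          # which.max: earliest tie
    }
    tibble::tibble(annotation = at, time = (idx - 1) / sample_rate,
                   amplitude = if (mode == "abs") abs(waveform[idx])
                               else waveform[idx])
  })
}

#' Segment typed events into trains
#'
#' Events of one type belong to the same train when their separation from
#' another event of that type is less than the type's threshold (strictly;
#' 200 ms for pulse, 400 ms for clack by default). Membership chains:
#' consecutive same-type events with gap strictly below threshold share a
#' train (single linkage), singletons form singleton trains, and types
#' never mix.
#'
#' @param events Tibble with columns `type` and `time` (s); unsorted input
#'   is sorted internally with a warning.
#' @param thresholds Named numeric thresholds in seconds
#'   (default `c(pulse = 0.2, clack = 0.4)`).
#' @return The events tibble, sorted by time, with a `train` id column
#'   (`"<type>_<k>"` in order of first event).
#' @examples
#' ev <- tibble::tibble(type = "pulse", time = c(0, 0.15, 0.30, 0.60))
#' segment_trains(ev)  # trains pulse_1 (3 events) and pulse_2 (1 event)
#' @export
segment_trains <- function(events, thresholds = c(pulse = 0.2, clack = 0.4)) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("type", "time") %in% names(events)))
  if (is.unsorted(events$time)) {
    warning("events were not sorted by time; sorting")
    events <- events[order(events$time), , drop = FALSE]
  }
  events$train <- NA_character_
  for (ty in unique(events$type)) {
    thr <- thresholds[[ty]]
    if (is.null(thr)) stop("no threshold for type: ", ty)
    idx <- which(events$type == ty)
    gaps <- diff(events$time[idx])
    new_train <- c(TRUE, gaps >= thr)         # strict <: gap == thr splits
    events$train[idx] <- sprintf("%s_%d", ty, cumsum(new_train))
  }
  events
}

#' Summary statistics of segmented song events
#'
#' Per event type: event and train counts, train sizes, within-train
#' inter-event intervals, and events per second of the spanned song time.
#'
#' @param events Output of [segment_trains()] (needs `type`, `time`,
#'   `train`).
#' @param courtship_s Optional denominator (s of courtship) for the event
#'   rate; defaults to the spanned time per type.
#' @return Tibble per type with `n_events`, `n_trains`, `train_sizes`
#'   (list), `ieis` (list, s), `mean_iei`, `events_per_s`.
#' @export
train_stats <- function(events, courtship_s = NULL) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) {
    return(tibble::tibble(type = character(), n_events = integer(),
                          n_trains = integer(), train_sizes = list(),
                          ieis = list(), mean_iei = numeric(),
                          events_per_s = numeric()))
  }
  stopifnot("train" %in% names(events))
  events |>
    dplyr::group_by(.data$type) |>
    dplyr::group_modify(function(d, key) {
      sizes <- as.integer(table(d$train))
      ieis <- unlist(lapply(split(d$time, d$train), function(tm) {
        if (length(tm) > 1) diff(sort(tm)) else numeric(0)
      }), use.names = FALSE)
      span <- if (!is.null(courtship_s)) courtship_s
              else max(d$time) - min(d$time)
      miei <- if (length(ieis)) mean(ieis) else NA_real_
      tibble::tibble(n_events = nrow(d),
                     n_trains = length(unique(d$train)),
                     train_sizes = list(sizes), ieis = list(ieis),
                     mean_iei = miei,
                     events_per_s = if (span > 0) nrow(d) / span
                                    else NA_real_)
    }) |>
    dplyr::ungroup()
}
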