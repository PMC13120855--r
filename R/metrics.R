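#' Sliding-window expressivity trace
#'
#' Per output frame `t`, the fraction of frames annotated as the action
#' within a centered window of `window_s` seconds, truncated at trial
#' edges with per-window renormalization (the denominator is the number of
#' available frames, so traces do not ramp down artificially at the
#' edges). Bouts of all flies in the table are pooled by union; filter by
#' `fly_id` beforehand for a per-fly trace.
#'
#' @param bouts Bout tibble.
#' @param action Action label.
#' @param window_s Window length in seconds (default 10).
#' @param frame_rate Frames per second.
#' @param duration Trial length in frames.
#' @return Object of class `expressivity_trace` (a tibble with `frame`,
#'   `time_s`, `fraction`).
#' @export
sliding_fraction <- function(bouts, action, window_s = 10, frame_rate,
                             duration) {
  stopifnot(window_s > 0, frame_rate > 0, duration > 0)
  ind <- frame_indicator(bouts[bouts$action == action, , drop = FALSE],
                         duration)
  wlen <- max(1L, round(window_s * frame_rate))  # window length in frames
  half_lo <- floor((wlen - 1) / 2)
  cs <- c(0L, cumsum(ind))
  t <- seq_len(duration)            # 1-based frame positions
  lo <- pmax(t - half_lo, 1L)
  hi <- pmin(t - half_lo + wlen - 1L, duration)
  frac <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- tibble::tibble(frame = t - 1L, time_s = (t - 1L) / frame_rate,
                        fraction = frac)
  structure(out, action = action, window_s = window_s,
            class = c("expressivity_trace", class(out)))
}

#' Group mean + SEM expressivity trace
#'
#' Averages per-trial [sliding_fraction()] traces frame-by-frame across
#' trials and attaches the standard error of the mean envelope.
#'
#' @param traces List of equal-length `expressivity_trace` objects.
#' @return Tibble `frame`, `time_s`, `mean`, `sem`, `n`.
#' @export
group_trace <- function(traces) {
  stopifnot(length(traces) >= 1)
  n <- length(traces)
  len <- nrow(traces[[1]])
  stopifnot(all(vapply(traces, nrow, integer(1)) == len))
  mat <- vapply(traces, function(tr) tr$fraction, numeric(len))
  mat <- matrix(mat, nrow = len)
  tibble::tibble(frame = traces[[1]]$frame, time_s = traces[[1]]$time_s,
                 mean = rowMeans(mat),
                 sem = if (n > 1) apply(mat, 1, stats::sd) / sqrt(n)
                       else rep(NA_real_, len),
                 n = n)
}

#' Plot an expressivity trace
#'
#' @param object An `expressivity_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expressivity_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$fraction)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("fraction of frames in %s",
                              attr(object, "action") %||% "action")) +
    ggplot2::theme_minimal()
}

# union length (in frames) of intervals of one action
union_frames <- function(bouts, action) {
  ab <- bouts[bouts$action == action, , drop = FALSE]
  if (!nrow(ab)) return(0L)
  ab <- ab[order(ab$start, ab$end), , drop = FALSE]
  total <- 0L
  cur_s <- ab$start[1]; cur_e <- ab$end[1]
  if (nrow(ab) > 1) {
    for (i in 2:nrow(ab)) {
      if (ab$start[i] <= cur_e) {
        cur_e <- max(cur_e, ab$end[i])
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- ab$start[i]; cur_e <- ab$end[i]
      }
    }
  }
  total + (cur_e - cur_s)
}

#' Fraction of time spent in an action
#'
#' Union length of the action's bouts divided by the effective trial
#' duration (the copulation latency when the trial was truncated). The
#' union keeps pooled two-fly totals at or below 1; set `per_fly = TRUE`
#' for one row per fly instead.
#'
#' @param bouts Bout tibble.
#' @param action Action label.
#' @param effective_duration Normalizing duration in frames (> 0).
#' @param per_fly If `TRUE`, return a tibble with one fraction per fly.
#' @return A proportion in `[0, 1]`, or a tibble when `per_fly = TRUE`.
#' @export
fraction_time <- function(bouts, action, effective_duration,
                          per_fly = FALSE) {
  if (effective_duration <= 0) stop("effective_duration must be positive")
  if (per_fly) {
    flies <- unique(bouts$fly_id)
    return(tibble::tibble(
      fly_id = flies,
      fraction = vapply(flies, function(f) {
        union_frames(bouts[bouts$fly_id == f, , drop = FALSE], action) /
          effective_duration
      }, numeric(1), USE.NAMES = FALSE)))
  }
  union_frames(bouts, action) / effective_duration
}

#' Event rate in events per minute
#'
#' Bout count of the action divided by the effective duration in minutes.
#'
#' @inheritParams fraction_time
#' @param frame_rate Frames per second.
#' @return Events per minute.
#' @export
event_rate <- function(bouts, action, effective_duration, frame_rate) {
  if (effective_duration <= 0) stop("effective_duration must be positive")
  minutes <- effective_duration / frame_rate / 60
  sum(bouts$action == action) / minutes
}

#' Latency to first bout of an action
#'
#' First onset of the action in seconds; when the action never occurs the
#' latency is censored at the effective duration (censored entries are
#' flagged, never dropped; downstream rank tests receive them at the
#' censoring value, the usual convention for fixed-length assays).
#'
#' @inheritParams event_rate
#' @return Tibble with `time_s` and `censored`.
#' @export
latency <- function(bouts, action, effective_duration, frame_rate) {
  ab <- bouts[bouts$action == action, , drop = FALSE]
  if (nrow(ab) == 0) {
    return(tibble::tibble(time_s = effective_duration / frame_rate,
                          censored = TRUE))
  }
  tibble::tibble(time_s = min(ab$start) / frame_rate, censored = FALSE)
}

#' Cumulative event curve
#'
#' Nondecreasing step function of the fraction of individuals having
#' performed the event by time t (e.g. cumulative copulation). Censored
#' entries never increment the curve; its final value is the overall event
#' rate (the natural input of a binomial test on the rate).
#'
#' @param latencies Tibble with columns `time_s` and `censored` (one row
#'   per individual), e.g. rows from [latency()].
#' @return Object of class `cumulative_curve`: tibble `time_s`, `fraction`
#'   (step knots, starting at (0, 0)), with attributes `n` and
#'   `final_rate`.
#' @export
cumulative_event_curve <- function(latencies) {
  latencies <- tibble::as_tibble(latencies)
  stopifnot(all(c("time_s", "censored") %in% names(latencies)))
  n <- nrow(latencies)
  ev <- sort(latencies$time_s[!latencies$censored])
  steps <- tibble::tibble(time_s = c(0, ev),
                          fraction = c(0, seq_along(ev)) / n)
  final <- length(ev) / n
  structure(steps, n = n, final_rate = final,
            class = c("cumulative_curve", class(steps)))
}

#' @param x A `cumulative_curve`.
#' @param ... Unused.
#' @rdname cumulative_event_curve
#' @export
glance.cumulative_curve <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), final_rate = attr(x, "final_rate"))
}

#' Plot a cumulative event curve
#'
#' @param object A `cumulative_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cumulative_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Plot a stimulus-locked fraction curve
#'
#' @param object A `ps_locked_curve` from [ps_locked_fraction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_locked_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$fraction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_line(color = "purple4") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time from PS onset (s)",
                  y = sprintf("fraction of flies in %s",
                              attr(object, "action") %||% "action")) +
    ggplot2::theme_minimal()
}
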