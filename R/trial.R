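#' Trial metadata
#'
#' A trial bundles everything about one recording that is not a bout: the
#' fly roster, the assay type, the video frame rate, the recording length in
#' frames, an optional copulation onset (frame at which analysis must end)
#' and an optional photostimulation protocol.
#'
#' Frames are 0-based and intervals are half-open `[start, end)`, so a trial
#' of `duration` frames covers frames `0 .. duration - 1` and a bout's
#' duration in seconds is `(end - start) / frame_rate`.
#'
#' @param trial_id Identifier string.
#' @param assay One of `"solitary"`, `"dyad"`, `"trio"`,
#'   `"group-large-chamber"`, `"ymaze"`, `"song"`.
#' @param frame_rate Frames per second (30 for standard video, 45 for the
#'   y-maze camera).
#' @param duration Trial length in frames.
#' @param roster Tibble/data.frame with columns `fly_id`, `sex` and
#'   optionally `strain`, `housing` (`"single"`/`"group"`), `genotype`,
#'   `wing_clipped`.
#' @param copulation_onset Optional frame index at which copulation began;
#'   must be `< duration`.
#' @param protocol Optional [ps_protocol()] object.
#' @return An object of class `dyadica_trial`.
#' @examples
#' trial("t1", "dyad", 30, 36000,
#'       roster = data.frame(fly_id = c("A", "B"), sex = c("M", "M")))
#' @export
trial <- function(trial_id, assay, frame_rate, duration, roster,
                  copulation_onset = NA_integer_, protocol = NULL) {
  assay <- match.arg(assay, c("solitary", "dyad", "trio",
                              "group-large-chamber", "ymaze", "song"))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 ||
      is.na(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be a single positive number")
  }
  stopifnot(is.numeric(duration), duration > 0)
  roster <- tibble::as_tibble(roster)
  stopifnot(all(c("fly_id", "sex") %in% names(roster)))
  expected_n <- switch(assay, solitary = 1L, dyad = 2L, trio = 3L, NA_integer_)
  if (!is.na(expected_n) && nrow(roster) != expected_n) {
    stop(sprintf("assay '%s' expects %d flies in roster, got %d",
                 assay, expected_n, nrow(roster)))
  }
  if (!is.na(copulation_onset)) {
    if (copulation_onset <= 0 || copulation_onset >= duration) {
      stop("copulation_onset must lie in (0, duration)")
    }
  }
  structure(list(
    trial_id = as.character(trial_id),
    assay = assay,
    frame_rate = as.numeric(frame_rate),
    duration = as.integer(duration),
    roster = roster,
    copulation_onset = as.integer(copulation_onset),
    protocol = protocol
  ), class = "dyadica_trial")
}

#' @export
print.dyadica_trial <- function(x, ...) {
  cat(sprintf("<dyadica_trial '%s'> %s assay, %g Hz, %d frames (%.1f s), %d flies\n",
              x$trial_id, x$assay, x$frame_rate, x$duration,
              x$duration / x$frame_rate, nrow(x$roster)))
  if (!is.na(x$copulation_onset)) {
    cat(sprintf("  copulation at frame %d (%.1f s)\n", x$copulation_onset,
                x$copulation_onset / x$frame_rate))
  }
  if (!is.null(x$protocol)) cat("  photostimulation protocol attached\n")
  invisible(x)
}

#' Validate a bout table against a trial and catalog
#'
#' Checks the bout-table invariants: known action labels, `end > start`,
#' bouts within `[0, duration]`, and no overlap between bouts of the same
#' fly and action. Returns the table sorted by start frame.
#'
#' @param bouts Tibble with columns `fly_id`, `action`, `start`, `end`
#'   (0-based half-open frame intervals).
#' @param trial A [trial()] object (or `NULL` to skip bound checks).
#' @param catalog An [action_catalog()] (or `NULL` to skip label checks).
#' @return The validated bout tibble, sorted by `start` then `fly_id`.
#' @export
validate_bouts <- function(bouts, trial = NULL, catalog = NULL) {
  bouts <- tibble::as_tibble(bouts)
  need <- c("fly_id", "action", "start", "end")
  missing <- setdiff(need, names(bouts))
  if (length(missing)) stop("bout table missing columns: ",
                            paste(missing, collapse = ", "))
  if (nrow(bouts) == 0) return(bouts)
  bad <- which(!(bouts$end > bouts$start))
  if (length(bad)) {
    stop(sprintf("bout row %d: end (%s) must exceed start (%s)",
                 bad[1], bouts$end[bad[1]], bouts$start[bad[1]]))
  }
  if (any(bouts$start < 0)) stop("negative start frame")
  if (!is.null(catalog)) {
    bad <- which(!bouts$action %in% catalog$action)
    if (length(bad)) {
      stop(sprintf("bout row %d: unknown action '%s'", bad[1],
                   bouts$action[bad[1]]))
    }
  }
  if (!is.null(trial)) {
    if (any(bouts$end > trial$duration)) {
      stop("bout extends past trial duration")
    }
    if (any(!bouts$fly_id %in% trial$roster$fly_id)) {
      stop("bout fly_id not in trial roster")
    }
  }
  bouts <- dplyr::arrange(bouts, .data$start, .data$fly_id, .data$action)
  # same-fly same-action bouts must not overlap (half-open intervals)
  ovl <- bouts |>
    dplyr::group_by(.data$fly_id, .data$action) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      bad = any(dplyr::lead(.data$start) < .data$end, na.rm = TRUE),
      .groups = "drop")
  if (any(ovl$bad)) {
    off <- ovl[which(ovl$bad)[1], ]
    stop(sprintf("overlapping bouts for fly '%s', action '%s'",
                 off$fly_id, off$action))
  }
  bouts
}
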